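#' Bounds for a Jeffreys-type parameter
#'
#' A Jeffreys-type parameter is strictly positive and as natural as its
#' reciprocal (stiffness vs compliance).  Inference is carried out on a
#' logarithmic rescaling of the parameter onto \eqn{[0, 1]}, so that the
#' noninformative density is constant and invariant under inversion of the
#' parameter.  Bounds delimit the physically reasonable range.
#'
#' @param name Parameter name (single string), e.g. `"mu"`.
#' @param lower,upper Strictly positive range limits, `0 < lower < upper`,
#'   in the parameter's physical units.
#' @param units Free-text unit label, e.g. `"Pa"`.
#' @return An object of class `param_bounds`.
#' @seealso [to_normalized()], [from_normalized()], [default_bounds()]
#' @export
#' @examples
#' b <- param_bounds("mu", 1e5, 1e7, "Pa")
#' to_normalized(1e6, b)   # geometric mean of the range -> 0.5
param_bounds <- function(name, lower, upper, units = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower), length(lower) == 1L,
            is.numeric(upper), length(upper) == 1L)
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || upper <= lower)
    stop("parameter bounds must satisfy 0 < lower < upper (Jeffreys-type ",
         "parameters are strictly positive)", call. = FALSE)
  structure(list(name = name, lower = lower, upper = upper, units = units),
            class = "param_bounds")
}

#' @export
print.param_bounds <- function(x, ...) {
  cat(sprintf("<param_bounds> %s in [%g, %g] %s\n",
              x$name, x$lower, x$upper, x$units))
  invisible(x)
}

#' Default parameter bounds for the viscoelastic models
#'
#' One decade on either side of the reference truth used throughout the
#' package's worked example (mu = 1 MPa, eta = 10 MPa s, A = 15 kPa), so the
#' truth sits at the centre of each normalized axis.  All values in SI units.
#'
#' @return Named list of [param_bounds()]: `mu` (Pa), `eta` (Pa s),
#'   `A` (Pa), `D` (Pa).
#' @export
default_bounds <- function() {
  list(mu  = param_bounds("mu",  1e5,   1e7,   "Pa"),
       eta = param_bounds("eta", 1e6,   1e8,   "Pa.s"),
       A   = param_bounds("A",   1.5e3, 1.5e5, "Pa"),
       D   = param_bounds("D",   1.5e3, 1.5e5, "Pa"))
}

#' Map a physical parameter value to its normalized coordinate
#'
#' Logarithmic change of variable
#' \deqn{\tilde m = \ln(m/m_{\inf}) / \ln(m_{\sup}/m_{\inf})}
#' mapping \eqn{[m_{\inf}, m_{\sup}]} onto \eqn{[0, 1]}.  The map sends a
#' parameter and its reciprocal (with reciprocal bounds) to mirror-image
#' coordinates, which is what makes a constant density on the unit cube
#' noninformative for Jeffreys-type parameters.
#'
#' @param m Physical value(s); must lie within the bounds.
#' @param b A [param_bounds()].
#' @return Normalized coordinate(s) in \eqn{[0, 1]}.
#' @export
to_normalized <- function(m, b) {
  stopifnot(inherits(b, "param_bounds"))
  if (any(!is.finite(m)) || any(m <= 0))
    stop("physical value must be finite and strictly positive", call. = FALSE)
  eps <- 1e-12
  if (any(m < b$lower * (1 - eps)) || any(m > b$upper * (1 + eps)))
    stop(sprintf("value outside bounds [%g, %g] for '%s'",
                 b$lower, b$upper, b$name), call. = FALSE)
  pmin(1, pmax(0, log(m / b$lower) / log(b$upper / b$lower)))
}

#' Map a normalized coordinate back to physical units
#'
#' Exact inverse of [to_normalized()]:
#' \eqn{m = m_{\inf} \exp(\tilde m \, \ln(m_{\sup}/m_{\inf}))}.
#'
#' @param mt Normalized coordinate(s) in \eqn{[0, 1]}.
#' @param b A [param_bounds()].
#' @return Physical value(s).
#' @export
from_normalized <- function(mt, b) {
  stopifnot(inherits(b, "param_bounds"))
  eps <- 1e-12
  if (any(!is.finite(mt)) || any(mt < -eps) || any(mt > 1 + eps))
    stop("normalized coordinate must lie in [0, 1]", call. = FALSE)
  b$lower * exp(pmin(1, pmax(0, mt)) * log(b$upper / b$lower))
}

#' Draw uniform samples on the unit cube
#'
#' Plain Monte-Carlo sampling of \eqn{[0,1]^d}; with a constant
#' (noninformative) density of unit mass on each hypothesis's cube, the
#' arithmetic mean of an integrand over these points estimates its integral,
#' and evidences of hypotheses of different dimensionality are directly
#' comparable.
#'
#' @param n Number of points (>= 1).
#' @param d Dimension (>= 1).
#' @param seed Optional integer seed; identical seeds give identical draws.
#'   The caller's RNG state is left untouched.
#' @return An `n x d` numeric matrix.
#' @export
sample_unit_cube <- function(n, d, seed = NULL) {
  stopifnot(length(n) == 1L, length(d) == 1L)
  n <- as.integer(n); d <- as.integer(d)
  if (is.na(n) || n < 1L) stop("n must be a positive integer", call. = FALSE)
  if (is.na(d) || d < 1L) stop("d must be a positive integer", call. = FALSE)
  with_seed(seed, matrix(stats::runif(n * d), nrow = n, ncol = d))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed kept within the 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt)) %% 2147483629)
}

# Map an n x d matrix of unit-cube points to physical parameter values.
# `bounds` is a named list of param_bounds covering `params`.
cube_to_physical <- function(points, params, bounds) {
  stopifnot(is.matrix(points), ncol(points) == length(params))
  missing <- setdiff(params, names(bounds))
  if (length(missing))
    stop("no bounds declared for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- points
  for (j in seq_along(params))
    out[, j] <- from_normalized(points[, j], bounds[[params[j]]])
  colnames(out) <- params
  out
}
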