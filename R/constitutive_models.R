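#' Stress-controlled triangular load protocol
#'
#' Loading and unloading at constant stress rate: the applied stress rises
#' linearly from 0 to `sigma_max` over `half_duration` seconds and returns
#' linearly to 0 over the second half, for a total test duration of
#' `2 * half_duration`.  Strain is recorded every `dt_sample` seconds.
#'
#' @param sigma_max Peak stress (Pa), > 0.  Default 1 MPa.
#' @param half_duration Ramp time T (s), > 0; total duration is 2T.
#' @param dt_sample Sampling interval (s), > 0 and <= 2T.
#' @return An object of class `load_protocol`.
#' @export
load_protocol <- function(sigma_max = 1e6, half_duration = 1, dt_sample = 0.1) {
  stopifnot(is.numeric(sigma_max), is.numeric(half_duration),
            is.numeric(dt_sample))
  if (sigma_max <= 0) stop("sigma_max must be > 0", call. = FALSE)
  if (half_duration <= 0) stop("half_duration must be > 0", call. = FALSE)
  if (dt_sample <= 0 || dt_sample > 2 * half_duration + 1e-12)
    stop("dt_sample must be in (0, 2*half_duration]", call. = FALSE)
  structure(list(sigma_max = sigma_max, half_duration = half_duration,
                 dt_sample = dt_sample),
            class = "load_protocol")
}

#' @export
print.load_protocol <- function(x, ...) {
  cat(sprintf("<load_protocol> 0 -> %g -> 0 Pa over %g s, sampled every %g s (%d samples)\n",
              x$sigma_max, 2 * x$half_duration, x$dt_sample, count_samples(x)))
  invisible(x)
}

#' Applied stress at a given time
#'
#' Piecewise-linear triangular wave:
#' \eqn{\sigma(t) = \sigma_{max} t/T} for \eqn{t \le T} and
#' \eqn{\sigma_{max}(2 - t/T)} for \eqn{t > T}.
#'
#' @param t Time(s) in \eqn{[0, 2T]} (vectorized).
#' @param p A [load_protocol()].
#' @return Stress (Pa).
#' @export
stress_at <- function(t, p) {
  stopifnot(inherits(p, "load_protocol"))
  T <- p$half_duration
  if (any(!is.finite(t)) || any(t < -1e-12) || any(t > 2 * T + 1e-9))
    stop("time outside the test window [0, 2T]", call. = FALSE)
  t <- pmin(pmax(t, 0), 2 * T)
  p$sigma_max * ifelse(t <= T, t / T, 2 - t / T)
}

#' Number of recorded samples in a protocol
#'
#' Sample instants are \eqn{t_k = k\,\Delta t}, \eqn{k = 0, \dots,
#' \lfloor 2T/\Delta t \rfloor}, including both endpoints when they fall on
#' the grid.  The reference protocol (2T = 2 s, dt = 0.1 s) has 21 samples.
#'
#' @param p A [load_protocol()].
#' @return Integer sample count.
#' @export
count_samples <- function(p) {
  stopifnot(inherits(p, "load_protocol"))
  as.integer(floor(2 * p$half_duration / p$dt_sample + 1e-9)) + 1L
}

#' Sample instants of a protocol
#' @param p A [load_protocol()].
#' @return Numeric vector of times (s).
#' @export
sample_times <- function(p) {
  (seq_len(count_samples(p)) - 1L) * p$dt_sample
}

# ---------------------------------------------------------------------------
# Hypothesis registry

.HYPOTHESES <- list(
  H1 = c("mu", "eta", "A"),        # Maxwell + 2nd-order Landau spring
  H2 = c("mu", "eta"),             # linear Maxwell
  H3 = c("mu"),                    # linear elastic
  H4 = c("mu", "eta", "A", "D"),   # Maxwell + 3rd-order Landau spring
  H5 = c("mu", "A")                # H1 with phenomenological eta(t) = 3 mu t
)

#' Constitutive-model hypotheses
#'
#' Five candidate scalar constitutive laws for a quasi-incompressible soft
#' tissue specimen under uniaxial stress control, differing in which physics
#' (viscosity, elastic nonlinearity) they include and hence in their active
#' parameters:
#'
#' * `H1` Maxwell viscoelasticity with a second-order Landau nonlinear
#'   spring: \eqn{\sigma = \mu \epsilon_e + A \epsilon_e^2},
#'   \eqn{d\epsilon_v/dt = \sigma/\eta},
#'   \eqn{\epsilon = \epsilon_e + \epsilon_v}.  Parameters `mu, eta, A`.
#' * `H2` Linear Maxwell: as H1 with no nonlinearity.  Parameters `mu, eta`.
#' * `H3` Linear elastic: \eqn{\sigma = \mu\epsilon}.  Parameter `mu`.
#' * `H4` As H1 plus a third-order term \eqn{D \epsilon_e^3}.
#'   Parameters `mu, eta, A, D`.
#' * `H5` H1 combined with a phenomenological law fixing the dynamic
#'   viscosity to \eqn{\eta(t) = 3\mu t} (t in seconds), leaving
#'   parameters `mu, A`.
#'
#' @param id One of `"H1" ... "H5"` (an existing `hypothesis` passes through).
#' @return An object of class `hypothesis` with fields `id` and `params`
#'   (ordered active parameter names).
#' @export
#' @examples
#' hypothesis("H1")$params   # "mu" "eta" "A"
hypothesis <- function(id) {
  if (inherits(id, "hypothesis")) return(id)
  stopifnot(is.character(id), length(id) == 1L)
  if (!id %in% names(.HYPOTHESES))
    stop(sprintf("unknown hypothesis '%s'; valid ids: %s", id,
                 paste(names(.HYPOTHESES), collapse = ", ")), call. = FALSE)
  structure(list(id = id, params = .HYPOTHESES[[id]]), class = "hypothesis")
}

#' @export
print.hypothesis <- function(x, ...) {
  cat(sprintf("<hypothesis> %s {%s}\n", x$id, paste(x$params, collapse = ", ")))
  invisible(x)
}

#' Ids of the available hypotheses
#' @return Character vector `c("H1", ..., "H5")`.
#' @export
hypothesis_ids <- function() names(.HYPOTHESES)

# ---------------------------------------------------------------------------
# Elastic spring

#' Elastic strain of the (non)linear Landau spring
#'
#' Solves \eqn{\sigma = \mu\epsilon + A\epsilon^2 + D\epsilon^3} for the root
#' continuous in (A, D) with the linear solution \eqn{\sigma/\mu}, by
#' safeguarded Newton iteration started at \eqn{\sigma/\mu} and bracketed in
#' \eqn{[0, \sigma/\mu]} (the polynomial is increasing and convex there for
#' nonnegative coefficients, so the root is unique).  Fully vectorized:
#' `sigma` may be a matrix with `mu`, `A`, `D` recycled down its columns.
#'
#' @param sigma Stress (Pa), >= 0; vector or matrix.
#' @param mu Shear modulus (Pa), > 0.
#' @param A Second-order nonlinearity (Pa), >= 0 (default 0 = linear).
#' @param D Third-order nonlinearity (Pa), >= 0 (default 0).
#' @param tol Relative convergence tolerance on the Newton step.
#' @param max_iter Iteration cap; non-converged entries are returned as `NA`
#'   and treated downstream as impossible model evaluations (zero
#'   information density).
#' @return Elastic strain, same shape as `sigma`.
#' @export
elastic_strain <- function(sigma, mu, A = 0, D = 0,
                           tol = 1e-13, max_iter = 100L) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(A < 0) || any(D < 0))
    stop("A and D must be >= 0 on the physical branch", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  e <- sigma / mu                      # exact in the linear limit
  if (all(A == 0) && all(D == 0)) return(e)
  hi <- e
  for (it in seq_len(max_iter)) {
    f  <- mu * e + A * e^2 + D * e^3 - sigma
    fp <- mu + 2 * A * e + 3 * D * e^2
    step <- f / fp
    e_new <- e - step
    # safeguard: the root lies in [0, sigma/mu]; fall back to bisection-like
    # midpoint if Newton leaves the bracket or misbehaves
    bad <- !is.finite(e_new) | e_new < 0 | e_new > hi
    if (any(bad)) e_new[bad] <- 0.5 * e[bad]
    done <- max(abs(e_new - e) / (1 + abs(e_new)))
    e <- e_new
    if (done < tol) break
  }
  f <- mu * e + A * e^2 + D * e^3 - sigma
  fail <- abs(f) > 1e-8 * (abs(sigma) + mu)
  if (any(fail)) e[fail] <- NA_real_
  e
}

# ---------------------------------------------------------------------------
# Viscous quadrature

# Cumulative integral of `fun` on [0, 2T] by the trapezoidal (Heun) rule on a
# fine grid of step ~dt_int that is forced to contain the ramp reversal T and
# every requested evaluation time.  Returns values at `t_eval`.
cum_quadrature <- function(fun, protocol, t_eval, dt_int = 1e-3) {
  T2 <- 2 * protocol$half_duration
  grid <- sort(unique(c(seq(0, T2, by = dt_int), T2,
                        protocol$half_duration, t_eval)))
  g <- fun(grid)
  dt <- diff(grid)
  cum <- c(0, cumsum(0.5 * dt * (g[-1] + g[-length(g)])))
  idx <- match(t_eval, grid)
  if (anyNA(idx)) {  # guard against numeric fuzz in t_eval
    idx <- vapply(t_eval, function(t) which.min(abs(grid - t)), integer(1))
  }
  cum[idx]
}

# Integral of the stress history: eps_v(t) = (1/eta) * int_0^t sigma.
stress_integral <- function(protocol, t_eval, dt_int = 1e-3) {
  cum_quadrature(function(t) stress_at(t, protocol), protocol, t_eval, dt_int)
}

# Integral of sigma(t)/(3 t) for the H5 time-varying viscosity; the t = 0
# singularity is removable under the ramp (sigma/t -> sigma_max/T), and the
# quadrature starts from that limit value.
h5_integral <- function(protocol, t_eval, dt_int = 1e-3) {
  T <- protocol$half_duration
  fun <- function(t) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- stress_at(t[pos], protocol) / (3 * t[pos])
    out[!pos] <- protocol$sigma_max / (3 * T)
    out
  }
  cum_quadrature(fun, protocol, t_eval, dt_int)
}

# ---------------------------------------------------------------------------
# Forward simulation

# Vectorized forward map: theta is an n x d matrix with columns named after
# the hypothesis's active parameters (physical units); returns an n x n_t
# matrix of strains at the protocol's sample times.  The viscous strain is a
# pure quadrature of the known stress history, computed once per protocol and
# scaled per sample; the elastic strain is the Landau-spring root.
forward_strains <- function(hyp, theta, protocol, dt_int = 1e-3) {
  hyp <- hypothesis(hyp)
  stopifnot(is.matrix(theta), all(hyp$params %in% colnames(theta)))
  tk <- sample_times(protocol)
  sk <- stress_at(tk, protocol)
  n  <- nrow(theta)
  S  <- matrix(sk, nrow = n, ncol = length(sk), byrow = TRUE)
  mu <- theta[, "mu"]
  el <- switch(hyp$id,
    H3 = ,
    H2 = S / mu,
    H1 = ,
    H5 = elastic_strain(S, mu, theta[, "A"]),
    H4 = elastic_strain(S, mu, theta[, "A"], theta[, "D"]))
  vi <- switch(hyp$id,
    H3 = 0,
    H5 = outer(1 / (mu), h5_integral(protocol, tk, dt_int)),
    outer(1 / theta[, "eta"], stress_integral(protocol, tk, dt_int)))
  el + vi
}

#' Simulate a stress-controlled test under one hypothesis
#'
#' Runs the forward model of `hyp` for one parameter set: the elastic strain
#' follows the Landau spring law and the viscous strain is accumulated by
#' trapezoidal (Heun) quadrature of \eqn{d\epsilon_v/dt = \sigma(t)/\eta(t)}
#' from \eqn{\epsilon_v(0) = 0} on a fine grid of step `dt_int` (the rate
#' depends only on the prescribed stress history, so the ODE is a pure
#' quadrature and second order is ample).  For `H3` the response is the
#' algebraic \eqn{\sigma/\mu}; for `H5` the viscosity is \eqn{\eta(t)=3\mu t}.
#'
#' @param hyp Hypothesis id or [hypothesis()].
#' @param params Named list/vector of physical parameter values (Pa, Pa s)
#'   covering the hypothesis's active parameters; inactive parameters are
#'   simply not consulted.
#' @param protocol A [load_protocol()].
#' @param dt_int Integration step (s), <= `dt_sample`; default `1e-3`.
#' @return A `data.frame` with columns `time_s`, `stress_Pa`, `strain`, plus
#'   attributes `elastic` and `viscous` holding the strain decomposition.
#' @export
#' @examples
#' p <- load_protocol()
#' s <- simulate_strain("H1", list(mu = 1e6, eta = 1e7, A = 1.5e4), p)
#' head(s)
simulate_strain <- function(hyp, params, protocol, dt_int = 1e-3) {
  hyp <- hypothesis(hyp)
  stopifnot(inherits(protocol, "load_protocol"))
  if (dt_int <= 0 || dt_int > protocol$dt_sample + 1e-12)
    stop("dt_int must be in (0, dt_sample]", call. = FALSE)
  params <- unlist(params)
  missing <- setdiff(hyp$params, names(params))
  if (length(missing))
    stop(sprintf("hypothesis %s requires parameter(s): %s", hyp$id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  theta <- matrix(params[hyp$params], nrow = 1,
                  dimnames = list(NULL, hyp$params))
  tk <- sample_times(protocol)
  sk <- stress_at(tk, protocol)
  eps <- drop(forward_strains(hyp, theta, protocol, dt_int))
  # strain decomposition for inspection
  el <- switch(hyp$id,
    H3 = ,
    H2 = sk / params[["mu"]],
    H4 = elastic_strain(sk, params[["mu"]], params[["A"]], params[["D"]]),
    elastic_strain(sk, params[["mu"]], params[["A"]]))
  out <- data.frame(time_s = tk, stress_Pa = sk, strain = eps)
  attr(out, "elastic") <- el
  attr(out, "viscous") <- eps - el
  out
}
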