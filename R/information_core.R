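#' Unnormalized information density
#'
#' An information density assigns to every point of a labelled variable space
#' a nonnegative plausibility, zero exactly when the point is impossible.
#' Unlike a probability density it is deliberately unnormalized: dropping the
#' normalization axiom is what lets two independent sources of information be
#' conjoined by a plain pointwise product and lets hypothesis spaces of
#' different dimensionality be compared after a single final rescaling.
#'
#' @param fn Function mapping a named list/vector point to a nonnegative
#'   scalar.
#' @param vars Character vector naming the variables of the density's space.
#' @return An object of class `info_density`.
#' @seealso [and_combine()], [or_combine()], [noninformative()]
#' @export
info_density <- function(fn, vars) {
  stopifnot(is.function(fn), is.character(vars), length(vars) >= 1L)
  structure(list(fn = fn, vars = sort(vars)), class = "info_density")
}

#' Evaluate an information density at a point
#' @param f An [info_density()].
#' @param x Point (named list or vector over `f$vars`).
#' @return Nonnegative scalar.
#' @export
density_eval <- function(f, x) {
  stopifnot(inherits(f, "info_density"))
  v <- f$fn(x)
  if (!is.finite(v) && !identical(v, Inf)) v <- 0
  if (v < 0) stop("information density returned a negative value", call. = FALSE)
  v
}

#' Noninformative density
#'
#' The constant density 1: the identity element of conjunction.  For
#' Jeffreys-type parameters mapped to the unit cube it carries unit mass per
#' hypothesis, which is what makes evidences across hypotheses comparable.
#'
#' @param vars Variable names of the space.
#' @return An [info_density()] identically 1.
#' @export
noninformative <- function(vars) info_density(function(x) 1, vars)

check_same_space <- function(f1, f2) {
  if (!identical(f1$vars, f2$vars))
    stop(sprintf("densities are defined over different variable spaces ({%s} vs {%s})",
                 paste(f1$vars, collapse = ","), paste(f2$vars, collapse = ",")),
         call. = FALSE)
}

#' Conjunction (AND) of two information densities
#'
#' The pointwise product: the plausibility that both sources of information
#' hold simultaneously.  Replaces the conditional update of Bayes' theorem;
#' impossibility (a zero) in either source absorbs.
#'
#' @param f1,f2 [info_density()] objects over the same variable space.
#' @return Their pointwise product as an [info_density()].
#' @export
and_combine <- function(f1, f2) {
  stopifnot(inherits(f1, "info_density"), inherits(f2, "info_density"))
  check_same_space(f1, f2)
  info_density(function(x) density_eval(f1, x) * density_eval(f2, x), f1$vars)
}

#' Disjunction (OR) of two information densities
#'
#' The pointwise sum (deliberately unnormalized, so 1 OR 1 = 2).
#'
#' @inheritParams and_combine
#' @return Their pointwise sum as an [info_density()].
#' @export
or_combine <- function(f1, f2) {
  stopifnot(inherits(f1, "info_density"), inherits(f2, "info_density"))
  check_same_space(f1, f2)
  info_density(function(x) density_eval(f1, x) + density_eval(f2, x), f1$vars)
}

# ---------------------------------------------------------------------------
# Gaussian particularization

#' Combined observation/model covariance
#'
#' The Gaussian particularization conjoins an observation density centred on
#' the measured strains (covariance `Co`) with a model density centred on the
#' simulated ones (covariance `Cm`); marginalizing over the latent
#' observation space leaves a single Gaussian with covariance `Co + Cm`.
#' Model error is typically negligible next to measurement noise, so
#' `Cm = 0` by default.
#'
#' @param obs_var Observation covariance `Co`: a vector of per-sample
#'   variances (diagonal case) or a full covariance matrix (strain^2).
#' @param model_var Model covariance `Cm`, same shape convention; default 0.
#' @return An object of class `covariance_model` with the combined
#'   covariance, which must be positive definite.
#' @export
covariance_model <- function(obs_var, model_var = 0) {
  diag_case <- !is.matrix(obs_var)
  if (diag_case) {
    if (length(model_var) == 1L) model_var <- rep(model_var, length(obs_var))
    if (is.matrix(model_var)) {
      comb <- diag(obs_var, length(obs_var)) + model_var
      diag_case <- FALSE
    } else comb <- obs_var + model_var
  } else {
    if (!is.matrix(model_var)) model_var <- diag(as.numeric(model_var), nrow(obs_var))
    comb <- obs_var + model_var
  }
  if (diag_case) {
    if (any(!is.finite(comb)) || any(comb <= 0))
      stop("combined covariance must be positive definite", call. = FALSE)
  } else {
    if (!isTRUE(all.equal(comb, t(comb))))
      stop("covariance matrix must be symmetric", call. = FALSE)
    ev <- eigen(comb, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("combined covariance must be positive definite", call. = FALSE)
  }
  structure(list(combined = comb, diagonal = diag_case),
            class = "covariance_model")
}

#' Gaussian misfit between simulated and observed strains
#'
#' The quadratic form
#' \deqn{J = \tfrac12 \sum_{ij} (\epsilon_i^{sim} - \epsilon_i^{obs})
#'   [(C^o + C^m)^{-1}]_{ij} (\epsilon_j^{sim} - \epsilon_j^{obs})}
#' over the discrete sample instants (a plain sum, with no dt weighting: the
#' compound information of independent samples is the product of the
#' per-sample Gaussians, which is a sum inside the exponential).  The
#' posterior information density on the parameters is then
#' \eqn{e^{-J}} up to normalization.
#'
#' @param sim Simulated strain vector (or a `data.frame` with a `strain`
#'   column).  `NA` entries mark failed model evaluations and give `J = Inf`.
#' @param obs Observed strain vector (or an `observation_set`).
#' @param cov A [covariance_model()]; if omitted and `obs` is an
#'   `observation_set`, its recorded per-sample variances are used.
#' @return Nonnegative scalar misfit `J` (dimensionless); `Inf` when the
#'   model evaluation is impossible.
#' @export
misfit <- function(sim, obs, cov = NULL) {
  if (is.data.frame(sim)) sim <- sim$strain
  if (inherits(obs, "observation_set")) {
    if (is.null(cov)) cov <- covariance_model(obs$strain_sd^2)
    obs <- obs$strain
  }
  if (is.null(cov)) stop("a covariance model is required", call. = FALSE)
  stopifnot(inherits(cov, "covariance_model"))
  if (length(sim) != length(obs))
    stop("simulated and observed series have different lengths", call. = FALSE)
  r <- sim - obs
  if (anyNA(r)) return(Inf)
  if (cov$diagonal) {
    if (length(cov$combined) != length(r))
      stop("covariance dimension does not match the series", call. = FALSE)
    0.5 * sum(r^2 / cov$combined)
  } else {
    0.5 * drop(crossprod(r, solve(cov$combined, r)))
  }
}

# Row-wise misfit for an n x n_t matrix of simulated strains against one
# observed series, diagonal covariance.  NA rows -> Inf.
misfit_rows <- function(E, obs, variances) {
  stopifnot(is.matrix(E), ncol(E) == length(obs),
            length(variances) == length(obs))
  R <- E - matrix(obs, nrow(E), length(obs), byrow = TRUE)
  J <- 0.5 * as.numeric((R * R) %*% (1 / variances))
  J[!is.finite(J) | is.na(J)] <- Inf
  bad <- rowSums(is.na(E)) > 0
  J[bad] <- Inf
  J
}

#' Posterior weight of a misfit value
#'
#' \eqn{e^{-J}}, in (0, 1]; an infinite misfit (impossible model evaluation)
#' maps to weight 0.
#'
#' @param J Nonnegative misfit value(s).
#' @return Weight(s) in \[0, 1\].
#' @export
posterior_weight <- function(J) {
  if (any(J < 0, na.rm = TRUE)) stop("misfit must be >= 0", call. = FALSE)
  exp(-J)
}

#' Monte-Carlo estimate of a unit-cube integral
#'
#' The arithmetic mean of integrand values evaluated at uniform unit-cube
#' samples estimates the integral over the cube; the standard error is the
#' sample standard deviation over \eqn{\sqrt N}.
#'
#' @param values Nonnegative integrand evaluations.
#' @return List with `estimate`, `se`, and `n`.
#' @seealso [mc_integral_log()] for an underflow-safe variant fed with
#'   log-integrand values.
#' @export
mc_integral <- function(values) {
  if (length(values) == 0L) stop("no integrand values supplied", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("integrand values must be nonnegative", call. = FALSE)
  list(estimate = mean(values),
       se = stats::sd(values) / sqrt(length(values)),
       n = length(values))
}

#' Underflow-safe Monte-Carlo integral from log-integrand values
#'
#' Computes `mean(exp(logv))` by shifting by the maximum before
#' exponentiating, so evidences remain finite even when every misfit is
#' large.  `-Inf` entries (impossible evaluations) contribute zero.
#'
#' @param logv Log-integrand values (e.g. `-J`).
#' @return List with `estimate`, `se`, `log_estimate`, and `n`.
#' @export
mc_integral_log <- function(logv) {
  if (length(logv) == 0L) stop("no integrand values supplied", call. = FALSE)
  m <- max(logv)
  if (!is.finite(m)) {          # every point impossible
    return(list(estimate = 0, se = 0, log_estimate = -Inf, n = length(logv)))
  }
  w <- exp(logv - m)
  est <- mean(w)
  list(estimate = est * exp(m),
       se = stats::sd(w) / sqrt(length(w)) * exp(m),
       log_estimate = m + log(est),
       n = length(logv))
}

#' Normalization constant of a posterior information density
#'
#' Given the integral `I` of \eqn{e^{-J}} over the parameter cube, the
#' constant \eqn{k = 1/I} rescales the information density into a classical
#' probability density of unit mass.
#'
#' @param I Positive integral value (or the list returned by
#'   [mc_integral()]).
#' @return The constant `1/I`.
#' @export
normalization_constant <- function(I) {
  if (is.list(I)) I <- I$estimate
  if (!is.finite(I) || I < 0) stop("integral must be a nonnegative finite number", call. = FALSE)
  if (I == 0)
    stop("integral is zero: every candidate model is impossible (falsified)",
         call. = FALSE)
  1 / I
}
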