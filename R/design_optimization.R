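#' Candidate design grid for the test duration
#'
#' Log-spaced grid of ramp times T over a search range; default 25 points
#' over \[0.2, 5\] s.
#'
#' @param lower,upper Range limits (s), 0 < lower < upper.
#' @param n Number of grid values (>= 1).
#' @return Numeric vector of durations.
#' @export
design_grid <- function(lower = 0.2, upper = 5, n = 25L) {
  stopifnot(lower > 0, upper > lower, n >= 1L)
  exp(seq(log(lower), log(upper), length.out = n))
}

#' Information gain over a grid of experimental designs
#'
#' Scans the design variable (here: the ramp time T of the triangular test;
#' the sampling interval stays fixed) and scores each candidate by the
#' information gain \eqn{f(S)}: the marginal of the joint information density
#' over parameters and observations at that design.  Before any experiment
#' exists the observation space is realized generatively — at each grid
#' duration, observations are synthesized from the reference truth with the
#' stated noise, and \eqn{f(S)} is estimated as the evidence
#' \eqn{I(T) = \int e^{-J} dM} on the hypothesis's unit cube, averaged over
#' `replicates` independent noise realizations to tame scan variance.
#' Gains are then normalized into \eqn{p(S)} (summing to 1 on the grid) and
#' per-design entropy terms are reported as a diagnostic.
#'
#' @param grid Candidate ramp times (s), e.g. [design_grid()].  Values
#'   yielding fewer than 2 samples are rejected.
#' @param hyp Hypothesis id or [hypothesis()]; default `"H1"`.
#' @param truth Named list of reference generating parameters (SI).
#' @param noise A [noise_spec()].
#' @param sigma_max Peak stress (Pa) of every candidate protocol.
#' @param dt_sample Sampling interval (s), fixed across designs.
#' @param replicates Noise realizations averaged per design; default 8.
#' @inheritParams reconstruct
#' @return A `design_scan` data frame with columns `duration_s`,
#'   `n_samples`, `gain` (mean evidence), `se` (between-replicate standard
#'   error), `p` (normalized), `entropy_term` (p log p, natural base), and
#'   attributes `optimal` (argmax duration), `entropy_total`, `seed`.
#' @export
design_gain <- function(grid = design_grid(), hyp = "H1",
                        truth = list(mu = 1e6, eta = 1e7, A = 1.5e4),
                        noise = noise_spec(), sigma_max = 1e6,
                        dt_sample = 0.1, replicates = 8L,
                        bounds = default_bounds(), N = 65536L, seed = 1L,
                        dt_int = 1e-3) {
  hyp <- hypothesis(hyp)
  stopifnot(length(grid) >= 1L, replicates >= 1L)
  d <- length(hyp$params)
  gain <- se <- numeric(length(grid))
  nsamp <- integer(length(grid))
  for (g in seq_along(grid)) {
    T <- grid[g]
    if (floor(2 * T / dt_sample + 1e-9) + 1 < 2)
      stop(sprintf("design T = %g s yields fewer than 2 samples at dt = %g s",
                   T, dt_sample), call. = FALSE)
    protocol <- load_protocol(sigma_max, T, dt_sample)
    nsamp[g] <- count_samples(protocol)
    U <- sample_unit_cube(N, d, derive_seed(seed, 7919L * g))
    theta <- cube_to_physical(U, hyp$params, bounds)
    E <- forward_strains(hyp, theta, protocol, dt_int)
    I_r <- numeric(replicates)
    for (r in seq_len(replicates)) {
      obs <- generate_observations(hyp, truth, protocol, noise,
                                   seed = derive_seed(seed, 104729L * g + r),
                                   dt_int = dt_int)
      J <- misfit_rows(E, obs$strain, obs$strain_sd^2)
      I_r[r] <- mc_integral_log(-J)$estimate
    }
    gain[g] <- mean(I_r)
    se[g] <- if (replicates > 1L) stats::sd(I_r) / sqrt(replicates) else NA_real_
  }
  if (sum(gain) == 0)
    stop("zero information gain across the whole grid", call. = FALSE)
  p <- gain / sum(gain)
  ent <- entropy_terms(p)
  out <- data.frame(duration_s = grid, n_samples = nsamp, gain = gain,
                    se = se, p = p, entropy_term = ent$terms)
  class(out) <- c("design_scan", "data.frame")
  attr(out, "optimal") <- optimal_design_value(grid, p)
  attr(out, "entropy_total") <- ent$total
  attr(out, "seed") <- seed
  attr(out, "hypothesis") <- hyp$id
  out
}

#' @export
print.design_scan <- function(x, ...) {
  cat(sprintf("<design_scan> %d designs over [%g, %g] s; optimal T = %.4g s\n",
              nrow(x), min(x$duration_s), max(x$duration_s),
              attr(x, "optimal")))
  invisible(x)
}

#' Entropy terms of normalized design probabilities
#'
#' Reports both the literal pointwise quantity \eqn{p \log_b p} per design
#' and the conventional signed total \eqn{-\sum_S p \log_b p}.  The log base
#' sets the unit: 2 for bits, e for nats (default), 10 for hartleys.
#' `0 log 0` is taken as 0.
#'
#' @param p Normalized probabilities (nonnegative, summing to 1 within
#'   `1e-8`).
#' @param base Logarithm base; default `exp(1)`.
#' @return List with `terms` (p log p, per design) and `total`
#'   (Shannon entropy, \eqn{-\sum p \log p}).
#' @export
entropy_terms <- function(p, base = exp(1)) {
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8)
    stop("probabilities must be normalized to 1", call. = FALSE)
  terms <- ifelse(p > 0, p * log(p, base = base), 0)
  list(terms = terms, total = -sum(terms))
}

optimal_design_value <- function(durations, p) {
  best <- which(p == max(p))
  min(durations[best])          # ties -> cheapest (shortest) test
}

#' Optimal design of a scan
#'
#' The design value attaining the maximum normalized information gain
#' \eqn{p(S)}; ties resolve to the smallest duration (the cheapest test).
#'
#' @param scan A [design_gain()] result.
#' @return Optimal duration (s).
#' @export
optimal_design <- function(scan) {
  stopifnot(inherits(scan, "design_scan"))
  optimal_design_value(scan$duration_s, scan$p)
}
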