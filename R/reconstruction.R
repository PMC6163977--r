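#' Posterior parameter reconstruction under one hypothesis
#'
#' Draws `N` uniform points on the hypothesis's normalized parameter cube,
#' maps them to physical values through the Jeffreys bounds, runs the forward
#' model at each, and attaches the Gaussian misfit `J` and posterior weight
#' \eqn{e^{-J}}.  With the constant noninformative density on the cube, these
#' weighted samples realize the (unnormalized) posterior information density
#' of the parameters given the hypothesis and the experimental design.
#'
#' @param hyp Hypothesis id or [hypothesis()].
#' @param obs An `observation_set` (see [generate_observations()] /
#'   [read_observations()]).
#' @param bounds Named list of [param_bounds()] covering the hypothesis's
#'   active parameters; default [default_bounds()].
#' @param N Monte-Carlo sample count; default `65536` (2^16).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param cov Optional [covariance_model()]; default: diagonal from the
#'   observation set's recorded per-sample variances, zero model covariance.
#' @param dt_int Forward-integration step (s).
#' @return An object of class `posterior_samples`: list with `hypothesis`,
#'   `points` (N x d normalized), `physical` (N x d), `J`, `log_weight`
#'   (= -J), `weight` (e^-J), `bounds`, `seed`, `N`, `obs`.
#'   Failed forward evaluations carry `J = Inf` (zero weight), never abort.
#' @export
#' @examples
#' obs <- generate_observations(seed = 1)
#' ps <- reconstruct("H1", obs, N = 4096, seed = 1)
#' point_estimate(ps)$joint_mode
reconstruct <- function(hyp, obs, bounds = default_bounds(), N = 65536L,
                        seed = 1L, cov = NULL, dt_int = 1e-3) {
  hyp <- hypothesis(hyp)
  stopifnot(inherits(obs, "observation_set"))
  protocol <- infer_protocol(obs)
  d <- length(hyp$params)
  U <- sample_unit_cube(N, d, seed)
  theta <- cube_to_physical(U, hyp$params, bounds)
  E <- forward_strains(hyp, theta, protocol, dt_int)
  if (ncol(E) != nrow(obs))
    stop("observation sample times do not match the protocol", call. = FALSE)
  J <- if (is.null(cov)) {
    misfit_rows(E, obs$strain, obs$strain_sd^2)
  } else {
    apply(E, 1L, misfit, obs = obs$strain, cov = cov)
  }
  structure(list(hypothesis = hyp, points = U, physical = theta, J = J,
                 log_weight = -J, weight = exp(-J), bounds = bounds,
                 seed = seed, N = as.integer(N), obs = obs,
                 dt_int = dt_int),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %s, N = %d, seed = %d, min J = %.3f\n",
              x$hypothesis$id, x$N, x$seed, min(x$J)))
  invisible(x)
}

# Relative weights exp(-(J - min J)): immune to underflow, proportional to
# the posterior weights, which is all marginals and modes need.
relative_weights <- function(ps) {
  jm <- min(ps$J)
  if (!is.finite(jm))
    stop("all posterior weights are zero: the hypothesis is falsified by the data",
         call. = FALSE)
  exp(-(ps$J - jm))
}

# Weighted quantile (type-1 step interpolation on the weighted ECDF).
weighted_quantile <- function(x, w, p = 0.5) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= p)[1]]
}

# Mode of a weighted sample on [0, 1] by boundary-reflected Gaussian KDE.
# The bandwidth follows Silverman's rule with the effective sample size
# (Kish) in place of n, floored at two mass bins, so that sharply peaked
# posteriors resolve below the histogram bin width while weakly informed,
# few-effective-sample marginals are smoothed rather than reporting the
# coordinate of a single heavy sample.
kde_mode_unit <- function(u, w, nbin = 1024L) {
  sw <- sum(w)
  ess <- sw^2 / sum(w^2)
  m1 <- sum(w * u) / sw
  sdw <- sqrt(sum(w * (u - m1)^2) / sw)
  iqr <- weighted_quantile(u, w, 0.75) - weighted_quantile(u, w, 0.25)
  sig <- min(sdw, iqr / 1.34)
  if (!is.finite(sig) || sig <= 0) sig <- max(sdw, 1e-6)
  h <- min(max(1.06 * sig * max(ess, 2)^(-1/5), 2 / nbin), 0.25)
  bin <- pmin(nbin, floor(u * nbin) + 1L)
  mass <- numeric(nbin)
  agg <- rowsum(w, bin)
  mass[as.integer(rownames(agg))] <- agg
  cb <- (seq_len(nbin) - 0.5) / nbin
  z <- outer(cb, cb, function(x, y)
    stats::dnorm((x - y) / h) + stats::dnorm((x + y) / h) +
      stats::dnorm((2 - x - y) / h))
  dens <- as.numeric(z %*% mass)
  cb[which.max(dens)]
}

#' One-dimensional weighted marginal of a posterior sample set
#'
#' Weighted histogram of one parameter's normalized coordinate, normalized to
#' unit area over \eqn{[0, 1]}.  The reported mode is the peak of a
#' boundary-reflected weighted kernel density estimate whose bandwidth
#' adapts to the effective sample size (sharp posteriors resolve below the
#' bin width; weakly informed marginals are smoothed instead of echoing a
#' single heavy sample); the peak of the lightly smoothed histogram is also
#' exposed (attribute `mode_hist`).  The median is the weighted 50% quantile
#' and the spread is the weighted standard deviation of the physical values.
#'
#' @param ps A [reconstruct()] result.
#' @param param Name of an active parameter of the hypothesis.
#' @param nbins Histogram bins over \eqn{[0,1]}; default 64.
#' @param smooth Moving-average window (odd, in bins) for mode extraction;
#'   `1` disables smoothing.
#' @return An object of class `marginal_curve`: `data.frame` with columns
#'   `coord` (bin centre, normalized), `value` (bin centre, physical units),
#'   `density` (unit area in normalized coordinates), and attributes `mode`,
#'   `median`, `sd` (physical units), `mode_coord`, `param`.
#' @export
marginal_1d <- function(ps, param, nbins = 64L, smooth = 3L) {
  stopifnot(inherits(ps, "posterior_samples"))
  idx <- match(param, ps$hypothesis$params)
  if (is.na(idx))
    stop(sprintf("parameter '%s' is not active in hypothesis %s", param,
                 ps$hypothesis$id), call. = FALSE)
  w <- relative_weights(ps)
  u <- ps$points[, idx]
  bin <- pmin(nbins, floor(u * nbins) + 1L)
  mass <- vapply(seq_len(nbins),
                 function(b) sum(w[bin == b]), numeric(1))
  width <- 1 / nbins
  dens <- mass / (sum(w) * width)
  sm <- if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    as.numeric(stats::filter(dens, k, sides = 2))
  } else dens
  # partial windows at the edges
  if (anyNA(sm)) {
    h <- (smooth - 1L) %/% 2L
    for (b in which(is.na(sm))) {
      lo <- max(1L, b - h); hi <- min(nbins, b + h)
      sm[b] <- mean(dens[lo:hi])
    }
  }
  centers <- (seq_len(nbins) - 0.5) * width
  b <- ps$bounds[[param]]
  phys <- from_normalized(centers, b)
  mode_bin <- which.max(sm)
  mode_u <- kde_mode_unit(u, w)
  xphys <- ps$physical[, param]
  med <- weighted_quantile(xphys, w, 0.5)
  mu_w <- sum(w * xphys) / sum(w)
  sd_w <- sqrt(sum(w * (xphys - mu_w)^2) / sum(w))
  out <- data.frame(coord = centers, value = phys, density = dens,
                    density_smooth = sm)
  attr(out, "param") <- param
  attr(out, "mode") <- from_normalized(mode_u, b)
  attr(out, "mode_coord") <- mode_u
  attr(out, "mode_hist") <- phys[mode_bin]
  attr(out, "median") <- med
  attr(out, "mean") <- mu_w
  attr(out, "sd") <- sd_w
  class(out) <- c("marginal_curve", "data.frame")
  out
}

#' @export
print.marginal_curve <- function(x, ...) {
  cat(sprintf("<marginal_curve> %s: mode %.4g, median %.4g, sd %.4g\n",
              attr(x, "param"), attr(x, "mode"), attr(x, "median"),
              attr(x, "sd")))
  invisible(x)
}

#' Summarize a marginal curve
#' @param object A [marginal_1d()] result.
#' @param ... Unused.
#' @return Named list with `param`, `mode`, `median`, `mean`, `sd`.
#' @export
summary.marginal_curve <- function(object, ...) {
  list(param = attr(object, "param"), mode = attr(object, "mode"),
       median = attr(object, "median"), mean = attr(object, "mean"),
       sd = attr(object, "sd"))
}

#' Two-dimensional plausibility slice
#'
#' Evaluates the unnormalized posterior weight \eqn{e^{-J}} on a regular
#' lattice in the normalized coordinates of two chosen parameters, clamping
#' every other active parameter at a fixed (typically most-probable) value.
#' This is the contour-plot view of how entangled a parameter pair is.
#'
#' @param hyp Hypothesis id or [hypothesis()] with at least two parameters.
#' @param obs An `observation_set`.
#' @param params Character pair: the two free parameters.
#' @param fixed Named list of physical values for the remaining active
#'   parameters (may be empty when the hypothesis has exactly two).
#' @param resolution Lattice points per axis; default 64.
#' @inheritParams reconstruct
#' @return List of class `plausibility_slice` with `x`, `y` (physical grid
#'   values), `xn`, `yn` (normalized), `weight` (resolution x resolution
#'   matrix of e^-J, unnormalized), `J`, `params`.
#' @export
joint_slice_2d <- function(hyp, obs, params, fixed = list(),
                           resolution = 64L, bounds = default_bounds(),
                           cov = NULL, dt_int = 1e-3) {
  hyp <- hypothesis(hyp)
  if (length(hyp$params) < 2L)
    stop(sprintf("hypothesis %s has a single parameter; a 2-D slice needs two free parameters",
                 hyp$id), call. = FALSE)
  stopifnot(length(params) == 2L)
  if (!all(params %in% hyp$params))
    stop("both slice parameters must be active in the hypothesis", call. = FALSE)
  rest <- setdiff(hyp$params, params)
  if (!all(rest %in% names(fixed)))
    stop("fixed values required for: ", paste(setdiff(rest, names(fixed)),
                                              collapse = ", "), call. = FALSE)
  protocol <- infer_protocol(obs)
  g <- (seq_len(resolution) - 0.5) / resolution
  grid <- expand.grid(xn = g, yn = g)
  theta <- matrix(NA_real_, nrow(grid), length(hyp$params),
                  dimnames = list(NULL, hyp$params))
  theta[, params[1]] <- from_normalized(grid$xn, bounds[[params[1]]])
  theta[, params[2]] <- from_normalized(grid$yn, bounds[[params[2]]])
  for (p in rest) theta[, p] <- fixed[[p]]
  E <- forward_strains(hyp, theta, protocol, dt_int)
  v <- if (is.null(cov)) obs$strain_sd^2 else NULL
  J <- if (is.null(cov)) misfit_rows(E, obs$strain, v) else
    apply(E, 1L, misfit, obs = obs$strain, cov = cov)
  W <- matrix(exp(-J), resolution, resolution)
  structure(list(x = from_normalized(g, bounds[[params[1]]]),
                 y = from_normalized(g, bounds[[params[2]]]),
                 xn = g, yn = g, weight = W,
                 J = matrix(J, resolution, resolution),
                 params = params, fixed = fixed),
            class = "plausibility_slice")
}

#' Point estimates from posterior samples
#'
#' The joint mode is approximated by the maximum-weight (minimum-misfit)
#' Monte-Carlo sample — ties broken by lowest sample index, so the estimate
#' is deterministic under a fixed seed — alongside the per-parameter marginal
#' modes from [marginal_1d()].
#'
#' @param ps A [reconstruct()] result.
#' @param nbins,smooth Passed to [marginal_1d()].
#' @return List with `joint_mode` (named physical vector), `joint_mode_J`,
#'   and `marginal_modes` (named vector).
#' @export
point_estimate <- function(ps, nbins = 64L, smooth = 3L) {
  stopifnot(inherits(ps, "posterior_samples"))
  if (!is.finite(min(ps$J)))
    stop("all posterior weights are zero: the hypothesis is falsified by the data",
         call. = FALSE)
  i <- which.min(ps$J)          # which.min returns the first minimum
  jm <- ps$physical[i, ]
  names(jm) <- ps$hypothesis$params
  mm <- vapply(ps$hypothesis$params,
               function(p) attr(marginal_1d(ps, p, nbins, smooth), "mode"),
               numeric(1))
  list(joint_mode = jm, joint_mode_J = ps$J[i], marginal_modes = mm)
}
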