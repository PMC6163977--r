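#' Evidence of a hypothesis
#'
#' The evidence \eqn{I_k} is the integral of the posterior weight
#' \eqn{e^{-J}} over the hypothesis's normalized parameter cube, estimated
#' as the Monte-Carlo mean over uniform cube samples.  Because every
#' hypothesis's noninformative density has unit mass on its own cube,
#' evidences of hypotheses with different numbers of parameters are directly
#' comparable, and extra dimensions that do not improve the fit dilute the
#' integrand — the built-in Occam penalty.
#'
#' @inheritParams reconstruct
#' @param samples Optional precomputed [reconstruct()] result to reuse
#'   (its `N`/`seed` then take precedence).
#' @return List with `value` (I), `se` (Monte-Carlo standard error), `log`
#'   (log I), `N`, and `hypothesis`.
#' @export
evidence <- function(hyp, obs, bounds = default_bounds(), N = 65536L,
                     seed = 1L, cov = NULL, dt_int = 1e-3, samples = NULL) {
  ps <- if (is.null(samples))
    reconstruct(hyp, obs, bounds, N, seed, cov, dt_int) else samples
  mc <- mc_integral_log(-ps$J)
  list(value = mc$estimate, se = mc$se, log = mc$log_estimate,
       N = ps$N, hypothesis = ps$hypothesis$id)
}

# Per-hypothesis RNG stream derived from one user seed, so rankings are
# reproducible yet streams are independent across hypotheses.
hypothesis_seed <- function(seed, id) {
  derive_seed(seed, 10007L * match(id, names(.HYPOTHESES)))
}

#' Rank competing hypotheses by plausibility
#'
#' Computes each hypothesis's evidence on the same observations and
#' normalizes (optionally against user prior weights) into plausibilities
#' \eqn{p(H_k) = f_o(H_k) I_k / \sum_j f_o(H_j) I_j}, summing to 1.
#' Each hypothesis uses its own RNG stream derived from `seed`.
#'
#' @param hypotheses Character vector of hypothesis ids (>= 2) or list of
#'   [hypothesis()] objects; default all five.
#' @param obs An `observation_set`.
#' @param prior Optional nonnegative prior weights, one per hypothesis
#'   (noninformative — all equal — when `NULL`).
#' @inheritParams reconstruct
#' @return A `hypothesis_ranking` data frame with columns `hypothesis`,
#'   `n_params`, `evidence`, `se`, `prior`, `plausibility`, `percent`,
#'   ordered as supplied.  Errors if every weighted evidence is zero (all
#'   candidate models falsified).
#' @export
#' @examples
#' obs <- generate_observations(seed = 1)
#' rank_hypotheses(c("H1", "H2", "H3"), obs, N = 4096, seed = 1)
rank_hypotheses <- function(hypotheses = hypothesis_ids(), obs,
                            bounds = default_bounds(), N = 65536L,
                            seed = 1L, prior = NULL, cov = NULL,
                            dt_int = 1e-3) {
  hyps <- lapply(hypotheses, hypothesis)
  if (length(hyps) < 2L)
    stop("ranking needs at least two hypotheses", call. = FALSE)
  if (is.null(prior)) prior <- rep(1, length(hyps))
  if (length(prior) != length(hyps) || any(prior < 0))
    stop("prior must be a nonnegative weight per hypothesis", call. = FALSE)
  ev <- lapply(hyps, function(h)
    evidence(h, obs, bounds, N, hypothesis_seed(seed, h$id), cov, dt_int))
  I <- vapply(ev, `[[`, numeric(1), "value")
  se <- vapply(ev, `[[`, numeric(1), "se")
  wI <- prior * I
  if (sum(wI) == 0)
    stop("every hypothesis has zero evidence: all candidate models are falsified",
         call. = FALSE)
  p <- wI / sum(wI)
  out <- data.frame(hypothesis = vapply(hyps, `[[`, character(1), "id"),
                    n_params = vapply(hyps, function(h) length(h$params),
                                      integer(1)),
                    evidence = I, se = se, prior = prior,
                    plausibility = p, percent = 100 * p)
  class(out) <- c("hypothesis_ranking", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "N") <- as.integer(N)
  out
}

#' @export
print.hypothesis_ranking <- function(x, ...) {
  cat("<hypothesis_ranking>\n")
  df <- as.data.frame(x)
  df$evidence <- signif(df$evidence, 4)
  df$se <- signif(df$se, 2)
  df$percent <- round(df$percent, 2)
  df$plausibility <- signif(df$plausibility, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Robust multi-hypothesis marginal of a shared parameter
#'
#' Rather than conditioning on a single model, mixes the per-hypothesis
#' marginal densities of a parameter with the hypothesis plausibilities as
#' weights (the discrete hypothesis space is summed over, not integrated).
#' A hypothesis in which the parameter is inactive contributes its
#' noninformative constant density, weighted by its plausibility.
#'
#' @param hypotheses Hypothesis ids (>= 1); the queried parameter must be
#'   active in at least one of them.
#' @param obs An `observation_set`.
#' @param param Parameter name to marginalize.
#' @param ranking Optional precomputed [rank_hypotheses()] result over the
#'   same hypotheses (computed internally when `NULL`; with a single
#'   hypothesis the mixture degenerates to its plain marginal).
#' @param nbins,smooth Histogram controls as in [marginal_1d()].
#' @inheritParams reconstruct
#' @return A `marginal_curve` over the parameter's normalized coordinate
#'   (mixture density, unit area), with `mode` (kernel estimate on the
#'   plausibility-pooled weighted sample), `median`, `sd` attributes
#'   computed from the mixture.
#' @export
robust_reconstruct <- function(hypotheses, obs, param,
                               bounds = default_bounds(), N = 65536L,
                               seed = 1L, ranking = NULL, nbins = 64L,
                               smooth = 3L, cov = NULL, dt_int = 1e-3) {
  hyps <- lapply(hypotheses, hypothesis)
  active <- vapply(hyps, function(h) param %in% h$params, logical(1))
  if (!any(active))
    stop(sprintf("parameter '%s' is active in none of the hypotheses", param),
         call. = FALSE)
  p_h <- if (length(hyps) == 1L) {
    1
  } else {
    if (is.null(ranking))
      ranking <- rank_hypotheses(hypotheses, obs, bounds, N, seed,
                                 cov = cov, dt_int = dt_int)
    stopifnot(inherits(ranking, "hypothesis_ranking"),
              nrow(ranking) == length(hyps))
    ranking$plausibility
  }
  width <- 1 / nbins
  centers <- (seq_len(nbins) - 0.5) * width
  mix <- numeric(nbins)
  mix_u <- mix_w <- numeric(0)   # pooled weighted sample for the mode
  for (k in seq_along(hyps)) {
    if (p_h[k] == 0) next
    if (active[k]) {
      ps <- reconstruct(hyps[[k]], obs, bounds, N,
                        hypothesis_seed(seed, hyps[[k]]$id), cov, dt_int)
      mc <- marginal_1d(ps, param, nbins, smooth = 1L)
      mix <- mix + p_h[k] * mc$density
      w <- relative_weights(ps)
      mix_u <- c(mix_u, ps$points[, match(param, hyps[[k]]$params)])
      mix_w <- c(mix_w, w * (p_h[k] / sum(w)))
    } else {
      mix <- mix + p_h[k] * rep(1, nbins)  # noninformative contribution
      mix_u <- c(mix_u, centers)
      mix_w <- c(mix_w, rep(p_h[k] / nbins, nbins))
    }
  }
  phys <- from_normalized(centers, bounds[[param]])
  sm <- if (smooth > 1L) {
    s <- as.numeric(stats::filter(mix, rep(1 / smooth, smooth), sides = 2))
    h <- (smooth - 1L) %/% 2L
    for (b in which(is.na(s)))
      s[b] <- mean(mix[max(1L, b - h):min(nbins, b + h)])
    s
  } else mix
  mass <- mix * width
  m1 <- sum(mass * phys); m2 <- sum(mass * phys^2)
  mode_u <- kde_mode_unit(mix_u, mix_w)
  out <- data.frame(coord = centers, value = phys, density = mix,
                    density_smooth = sm)
  attr(out, "param") <- param
  attr(out, "mode") <- from_normalized(mode_u, bounds[[param]])
  attr(out, "mode_coord") <- mode_u
  attr(out, "mode_hist") <- phys[which.max(sm)]
  attr(out, "median") <- phys[which(cumsum(mass) >= 0.5)[1]]
  attr(out, "mean") <- m1
  attr(out, "sd") <- sqrt(max(0, m2 - m1^2))
  attr(out, "plausibilities") <- p_h
  class(out) <- c("marginal_curve", "data.frame")
  out
}
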