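# Shared fixtures: the reference truth and handy constructors.

ref_truth <- list(mu = 1e6, eta = 1e7, A = 1.5e4)

ref_obs <- function(seed = 1L, noise = noise_spec(), protocol = load_protocol()) {
  generate_observations("H1", ref_truth, protocol, noise, seed = seed)
}

# Build a posterior_samples object directly from coordinates and misfits,
# bypassing the forward model (for testing the summary machinery on known
# weight shapes).
manual_posterior <- function(hyp, U, J, bounds = default_bounds()) {
  hyp <- hypothesis(hyp)
  stopifnot(ncol(U) == length(hyp$params))
  theta <- cube_to_physical(U, hyp$params, bounds)
  structure(list(hypothesis = hyp, points = U, physical = theta, J = J,
                 log_weight = -J, weight = exp(-J), bounds = bounds,
                 seed = NA_integer_, N = nrow(U), obs = NULL, dt_int = 1e-3),
            class = "posterior_samples")
}
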