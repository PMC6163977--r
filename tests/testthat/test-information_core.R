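test_that("AND/OR algebra matches the Boolean truth table and drops normalization", {
  ni <- noninformative("x")
  g1 <- info_density(function(x) exp(-(x$x - 0)^2 / 2), "x")
  g2 <- info_density(function(x) exp(-(x$x - 2)^2 / 2), "x")
  zero <- info_density(function(x) 0, "x")
  pt <- list(x = 0.7)
  # identity and absorption
  expect_equal(density_eval(and_combine(ni, g2), pt), density_eval(g2, pt))
  expect_equal(density_eval(and_combine(zero, g2), pt), 0)
  expect_equal(density_eval(or_combine(zero, g2), pt), density_eval(g2, pt))
  # 1 OR 1 = 2: unnormalized on purpose
  expect_equal(density_eval(or_combine(ni, ni), pt), 2)
  # commutativity and associativity at random points
  set.seed(3)
  for (v in runif(5, -3, 3)) {
    q <- list(x = v)
    expect_equal(density_eval(and_combine(g1, g2), q),
                 density_eval(and_combine(g2, g1), q))
    expect_equal(density_eval(or_combine(g1, g2), q),
                 density_eval(or_combine(g2, g1), q))
    a1 <- and_combine(and_combine(g1, g2), ni)
    a2 <- and_combine(g1, and_combine(g2, ni))
    expect_equal(density_eval(a1, q), density_eval(a2, q))
  }
  # mismatched spaces refuse to combine
  expect_error(and_combine(g1, info_density(function(x) 1, "y")),
               "different variable spaces")
})

test_that("conjoining two Gaussian shapes gives the product-Gaussian", {
  # unit-variance shapes centred 0 and 2 -> shape centred 1 with variance 1/2
  g1 <- info_density(function(x) exp(-(x$x - 0)^2 / 2), "x")
  g2 <- info_density(function(x) exp(-(x$x - 2)^2 / 2), "x")
  prod <- and_combine(g1, g2)
  target <- function(v) exp(-(v - 1)^2 / (2 * 0.5))
  grid <- seq(-1, 3, by = 0.25)
  ratios <- vapply(grid, function(v) density_eval(prod, list(x = v)) / target(v),
                   numeric(1))
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-12)
})

test_that("misfit is the half quadratic form in the combined covariance", {
  expect_equal(misfit(1:5 / 10, 1:5 / 10, covariance_model(rep(1, 5))), 0)
  expect_equal(misfit(0.1, 0.0, covariance_model(0.01)), 0.5)
  expect_equal(misfit(rep(0.01, 21), rep(0, 21), covariance_model(rep(1e-4, 21))),
               10.5)
  expect_error(misfit(1:3, 1:4, covariance_model(rep(1, 4))),
               "different lengths")
  # full covariance path agrees with an explicit solve
  set.seed(5)
  L <- matrix(rnorm(9), 3, 3); C <- crossprod(L) + diag(3)
  r <- rnorm(3)
  expect_equal(misfit(r, rep(0, 3), covariance_model(C)),
               0.5 * drop(t(r) %*% solve(C) %*% r))
  expect_error(covariance_model(c(1, -1)), "positive definite")
  # NA simulation (failed forward model) is an impossible point
  expect_equal(misfit(c(NA, 1), c(0, 1), covariance_model(c(1, 1))), Inf)
})

test_that("posterior weight is exp(-J), monotone, with Inf mapping to zero", {
  expect_equal(posterior_weight(0), 1)
  expect_equal(posterior_weight(log(2)), 0.5)
  expect_equal(posterior_weight(Inf), 0)
  J <- sort(runif(10, 0, 5))
  expect_true(all(diff(posterior_weight(J)) <= 0))
  expect_error(posterior_weight(-1), ">= 0")
})

test_that("Monte-Carlo integration estimates unit-cube integrals", {
  expect_equal(mc_integral(rep(3.7, 100))$estimate, 3.7)
  u <- sample_unit_cube(1e5, 1, seed = 2)
  mc <- mc_integral(drop(u))
  expect_lt(abs(mc$estimate - 0.5), 4 * mc$se)
  u2 <- sample_unit_cube(1e5, 2, seed = 3)
  mc2 <- mc_integral(u2[, 1] * u2[, 2])
  expect_lt(abs(mc2$estimate - 0.25), 4 * mc2$se)
  expect_error(mc_integral(numeric(0)), "no integrand")
  expect_error(mc_integral(c(1, -2)), "nonnegative")
})

test_that("log-domain integration agrees with the linear path and survives underflow", {
  set.seed(9)
  J <- runif(1000, 0, 20)
  lin <- mc_integral(exp(-J))
  logd <- mc_integral_log(-J)
  expect_equal(logd$estimate, lin$estimate, tolerance = 1e-12)
  expect_equal(logd$se, lin$se, tolerance = 1e-12)
  # shifted far into underflow territory the log estimate survives
  deep <- mc_integral_log(-J - 5000)
  expect_equal(deep$log_estimate, logd$log_estimate - 5000, tolerance = 1e-9)
  allzero <- mc_integral_log(rep(-Inf, 10))
  expect_equal(allzero$estimate, 0)
})

test_that("normalization constant is 1/I and zero evidence signals falsification", {
  expect_equal(normalization_constant(2), 0.5)
  expect_equal(normalization_constant(1), 1)
  expect_equal(normalization_constant(mc_integral(rep(4, 10))), 0.25)
  expect_error(normalization_constant(0), "impossible")
})

test_that("marginalizing the observation conjunction reproduces the Co+Cm Gaussian", {
  # 2-sample toy: integrate f_o(O) f_m(O|sim) over the latent observation
  # plane by brute-force quadrature and compare with exp(-J) under Co + Cm
  obs <- c(0.30, 0.55)
  Co <- c(0.02^2, 0.03^2); Cm <- c(0.015^2, 0.01^2)
  comb <- covariance_model(Co, Cm)
  oo <- seq(-0.3, 1.2, length.out = 401)   # +-8 sd around everything
  d <- oo[2] - oo[1]
  brute <- function(sim) {
    f1 <- outer(exp(-(oo - obs[1])^2 / (2 * Co[1])),
                exp(-(oo - obs[2])^2 / (2 * Co[2])))
    f2 <- outer(exp(-(oo - sim[1])^2 / (2 * Cm[1])),
                exp(-(oo - sim[2])^2 / (2 * Cm[2])))
    sum(f1 * f2) * d^2
  }
  sims <- list(c(0.30, 0.55), c(0.25, 0.60), c(0.35, 0.50), c(0.32, 0.57))
  ratio <- vapply(sims, function(s)
    brute(s) / exp(-misfit(s, obs, comb)), numeric(1))
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
})

test_that("normalized information density equals the Bayesian posterior exactly", {
  # H3 forward model, Gaussian likelihood, uniform prior on the unit cube:
  # the normalized e^{-J} and the normalized likelihood agree pointwise to
  # within 1e-10 relative (they differ by a multiplicative constant only)
  obs <- ref_obs(seed = 4)
  b <- default_bounds()
  grid <- seq(0.05, 0.95, length.out = 41)
  mu <- from_normalized(grid, b$mu)
  p <- viscoinfer:::infer_protocol(obs)
  J <- vapply(mu, function(m)
    misfit(simulate_strain("H3", list(mu = m), p), obs$strain,
           covariance_model(obs$strain_sd^2)), numeric(1))
  f_info <- exp(-(J - min(J)))          # information route (rescaled)
  lik <- vapply(seq_along(mu), function(i)
    prod(stats::dnorm(obs$strain,
                      simulate_strain("H3", list(mu = mu[i]), p)$strain,
                      obs$strain_sd)), numeric(1))
  post <- lik / sum(lik)                # Bayes route, uniform prior
  f_norm <- f_info / sum(f_info)
  expect_lt(max(abs(f_norm - post) / pmax(post, 1e-300)), 1e-10)
})
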