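test_that("triangular stress history is piecewise linear with the right anchors", {
  p <- load_protocol(sigma_max = 1e6, half_duration = 1, dt_sample = 0.1)
  expect_equal(stress_at(0, p), 0)
  expect_equal(stress_at(1, p), 1e6)
  expect_equal(stress_at(2, p), 0)
  expect_equal(stress_at(0.25, p), 0.25e6)
  expect_equal(stress_at(1.5, p), 0.5e6)
  expect_error(stress_at(-0.1, p), "test window")
  expect_error(stress_at(2.3, p), "test window")
})

test_that("sample counting includes both endpoints and resists float fuzz", {
  expect_equal(count_samples(load_protocol(1e6, 1, 0.1)), 21L)
  expect_equal(count_samples(load_protocol(1e6, 1, 2)), 2L)
  expect_equal(count_samples(load_protocol(1e6, 0.5, 0.1)), 11L)
  expect_equal(count_samples(load_protocol(1e6, 0.35, 0.1)), 8L)
  expect_equal(sample_times(load_protocol(1e6, 1, 0.1)),
               seq(0, 2, by = 0.1))
})

test_that("hypothesis registry exposes the five laws and their parameter sets", {
  expect_equal(hypothesis("H1")$params, c("mu", "eta", "A"))
  expect_equal(hypothesis("H2")$params, c("mu", "eta"))
  expect_equal(hypothesis("H3")$params, "mu")
  expect_equal(hypothesis("H4")$params, c("mu", "eta", "A", "D"))
  expect_equal(hypothesis("H5")$params, c("mu", "A"))
  expect_error(hypothesis("H9"), "H1, H2, H3, H4, H5")
})

test_that("elastic strain solves the Landau spring on the physical branch", {
  # linear limit and zero stress
  expect_equal(elastic_strain(0.5e6, 1e6), 0.5)
  expect_equal(elastic_strain(0, 1e6, 1.5e4), 0)
  # quadratic case against the closed-form root (independent oracle)
  quad_root <- function(sigma, mu, A) (-mu + sqrt(mu^2 + 4 * A * sigma)) / (2 * A)
  for (sig in c(1e5, 5e5, 1e6)) {
    expect_equal(elastic_strain(sig, 1e6, 1.5e4), quad_root(sig, 1e6, 1.5e4),
                 tolerance = 1e-10)
  }
  # root of 0.015 e^2 + e - 1 = 0 (value frozen from the quadratic formula)
  expect_equal(elastic_strain(1e6, 1e6, 1.5e4), 0.9854338033,
               tolerance = 1e-9)
  # cubic case against polyroot (independent oracle)
  mu <- 1e6; A <- 1.5e4; D <- 4e4; sig <- 0.8e6
  roots <- polyroot(c(-sig, mu, A, D))
  real_roots <- Re(roots[abs(Im(roots)) < 1e-6 * Mod(roots)])
  oracle <- min(real_roots[real_roots > 0])
  expect_equal(elastic_strain(sig, mu, A, D), oracle, tolerance = 1e-10)
  # continuity with the linear solution as A -> 0
  expect_equal(elastic_strain(1e6, 1e6, 1e-6), 1, tolerance = 1e-9)
  # matrix input with per-row parameters
  S <- matrix(c(1e5, 1e6, 2e5, 8e5), 2, 2)
  out <- elastic_strain(S, c(1e6, 2e6), c(1.5e4, 0))
  expect_equal(dim(out), dim(S))
  expect_equal(out[2, ], S[2, ] / 2e6)
  expect_error(elastic_strain(1e5, -1), "mu must be")
})

test_that("H3 is purely algebraic and H2 matches its ramp closed form", {
  p <- load_protocol()
  s3 <- simulate_strain("H3", list(mu = 1e6), p)
  expect_equal(s3$strain, s3$stress_Pa / 1e6)
  # H2 under the ramp branch: eps = r t / mu + r t^2 / (2 eta)
  s2 <- simulate_strain("H2", list(mu = 1e6, eta = 1e7), p, dt_int = 1e-3)
  tk <- s2$time_s
  r <- 1e6
  load <- tk <= 1
  closed_load <- r * tk[load] / 1e6 + r * tk[load]^2 / (2 * 1e7)
  expect_lt(max(abs(s2$strain[load] - closed_load)), 1e-4)
  expect_equal(s2$strain[tk == 1], 1.05, tolerance = 1e-4)
  # unloading branch closed form from the integrated triangle
  un <- tk > 1
  Q <- 1e6 * (0.5 + 2 * (tk[un] - 1) - (tk[un]^2 - 1) / 2)
  closed_un <- s2$stress_Pa[un] / 1e6 + Q / 1e7
  expect_lt(max(abs(s2$strain[un] - closed_un)), 1e-4)
})

test_that("model nesting holds: H4|D=0 = H1, H1|A->0 = H2, H2|eta->inf -> H3", {
  p <- load_protocol()
  th1 <- cbind(mu = 1e6, eta = 1e7, A = 1.5e4)
  th4 <- cbind(th1, D = 0)
  e1 <- viscoinfer:::forward_strains("H1", th1, p)
  e4 <- viscoinfer:::forward_strains("H4", th4, p)
  expect_equal(e4, e1, tolerance = 1e-12)
  th2 <- cbind(mu = 1e6, eta = 1e7)
  e2 <- viscoinfer:::forward_strains("H2", th2, p)
  e1a <- viscoinfer:::forward_strains("H1", cbind(mu = 1e6, eta = 1e7, A = 1e-9), p)
  expect_lt(max(abs(e1a - e2)), 1e-10)
  e2inf <- viscoinfer:::forward_strains("H2", cbind(mu = 1e6, eta = 1e12), p)
  e3 <- viscoinfer:::forward_strains("H3", cbind(mu = 1e6), p)
  expect_lt(max(abs(e2inf - e3)), 1e-3)
})

test_that("viscous quadrature is second order on a smooth integrand (H5)", {
  p <- load_protocol()
  tk <- sample_times(p)
  # analytic integral of sigma/(3 t): loading sigma_max t/(3T); unloading
  # (sigma_max/3)(2 log(t/T) - (t - T)/T) added to the loading part
  analytic <- ifelse(tk <= 1, 1e6 * tk / 3,
                     1e6 / 3 + (1e6 / 3) * (2 * log(pmax(tk, 1)) - (tk - 1)))
  err <- function(dt) max(abs(viscoinfer:::h5_integral(p, tk, dt) - analytic))
  e1 <- err(4e-3); e2 <- err(2e-3)
  expect_gt(e1 / e2, 2.5)   # halving the step cuts the error ~4x
})

test_that("H5 substitutes eta(t) = 3 mu t and starts from the removable limit", {
  p <- load_protocol()
  s5 <- simulate_strain("H5", list(mu = 1e6, A = 1.5e4), p)
  # loading: viscous strain = sigma_max t / (3 mu T), linear in t
  visc <- attr(s5, "viscous")
  tk <- s5$time_s
  expect_equal(visc[tk <= 1], 1e6 * tk[tk <= 1] / (3 * 1e6),
               tolerance = 1e-5)
  expect_equal(s5$strain[1], 0)
})

test_that("finite viscosity produces loading/unloading hysteresis", {
  p <- load_protocol()
  s <- simulate_strain("H1", ref_truth, p)
  tk <- s$time_s
  for (sig_frac in c(0.2, 0.5, 0.8)) {
    t_load <- sig_frac; t_unload <- 2 - sig_frac
    eps_l <- s$strain[abs(tk - t_load) < 1e-9]
    eps_u <- s$strain[abs(tk - t_unload) < 1e-9]
    expect_gt(eps_u, eps_l)   # viscous accumulation on the return branch
  }
})
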