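test_that("beta moment matching solves the shape equations", {
  # Beta(1, 1) is the uniform on (0, 1)
  expect_equal(beta_from_moments(0.5, sqrt(1 / 12)),
               c(alpha = 1, beta = 1))
  sh <- beta_from_moments(0.211, 0.109)
  expect_equal(unname(sh), c(2.7455, 10.2665), tolerance = 1e-4)
  sh2 <- beta_from_moments(0.147, 0.085)
  expect_equal(unname(sh2), c(2.4042, 13.9501), tolerance = 1e-4)
})

test_that("beta shapes reproduce the target moments under the beta's own formulas", {
  # independent inverse check via the distribution's closed-form moments
  cases <- list(c(0.211, 0.109), c(0.147, 0.085), c(0.006, 0.002),
                c(0.9, 0.05), c(0.05, 0.02))
  for (ms in cases) {
    sh <- beta_from_moments(ms[1], ms[2])
    a <- sh[["alpha"]]; b <- sh[["beta"]]
    expect_equal(a / (a + b), ms[1], tolerance = 1e-12)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), ms[2],
                 tolerance = 1e-12)
  }
  expect_error(beta_from_moments(0.5, 0.6), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "0 < mean < 1")
})

test_that("uniform moment matching returns mean +/- sqrt(3) sd", {
  expect_equal(uniform_from_moments(50, 0), c(lower = 50, upper = 50))
  expect_equal(uniform_from_moments(0, 1 / sqrt(12)),
               c(lower = -0.5, upper = 0.5))
  b <- uniform_from_moments(70.25, 5.93)
  expect_equal(unname(b), c(59.98, 80.52), tolerance = 1e-3)
  # the implied uniform has the requested moments
  expect_equal(mean(b), 70.25)
  expect_equal((b[["upper"]] - b[["lower"]]) / sqrt(12), 5.93)
})

test_that("draws are reproducible and degenerate inputs collapse to points", {
  cfg <- psa_config(n_sims = 500, seed = 99)
  d1 <- sample_draws(fixture_specs(), cfg)
  d2 <- sample_draws(fixture_specs(), cfg)
  expect_identical(d1$dalys, d2$dalys)
  expect_identical(d1$total, d2$total)

  point <- outcome_spec("pt", c(40, 0), c(48, 0), c(0.2, 0))
  d <- sample_draws(list(point), psa_config(n_sims = 50, seed = 1))
  expect_true(all(d$ard == 8))
  expect_true(all(d$dalys == dalys_averted(8, 0.2)))
})

test_that("per-simulation totals equal the row sums of outcome columns", {
  for (fam in c("normal", "beta", "uniform")) {
    d <- sample_draws(fixture_specs(),
                      psa_config(n_sims = 200, seed = 7, risk_family = fam))
    expect_equal(d$total, rowSums(d$dalys))
  }
})

test_that("each family recovers the specified moments within Monte Carlo error", {
  n <- 1e5
  spec <- gbv_spec()
  for (fam in c("normal", "beta", "uniform")) {
    d <- sample_draws(list(spec), psa_config(n_sims = n, seed = 11,
                                             risk_family = fam))
    for (col in c("risk_control", "risk_intervention")) {
      target <- spec[[col]]
      x <- d[[col]][, 1]
      se_mean <- target[["sd"]] / sqrt(n)
      expect_lt(abs(mean(x) - target[["mean"]]), 4 * se_mean)
      # SE of the sd estimate ~ sd/sqrt(2n)
      expect_lt(abs(stats::sd(x) - target[["sd"]]),
                4 * target[["sd"]] / sqrt(2 * n))
    }
    dw <- d$dw[, 1]
    expect_lt(abs(mean(dw) - 0.211), 4 * 0.109 / sqrt(n))
    expect_lt(abs(stats::sd(dw) - 0.109), 4 * 0.109 / sqrt(2 * n))
  }
})

test_that("beta and uniform risk draws respect their supports", {
  spec <- gbv_spec()
  d <- sample_draws(list(spec), psa_config(n_sims = 2e4, seed = 3,
                                           risk_family = "beta"))
  expect_true(all(d$risk_control > 0 & d$risk_control < 100))
  expect_true(all(d$dw > 0 & d$dw < 1))
  d <- sample_draws(list(spec), psa_config(n_sims = 2e4, seed = 3,
                                           risk_family = "uniform"))
  b <- uniform_from_moments(spec$risk_control[["mean"]], spec$risk_control[["sd"]])
  expect_true(all(d$risk_control >= b[["lower"]] & d$risk_control <= b[["upper"]]))
})

test_that("mean DALY draws converge to the product of expectations", {
  # risks and weights are independent, so E[(ARD/100) dw] = E[ARD]/100 E[dw]
  d <- sample_draws(list(gbv_spec()), psa_config(n_sims = 1e4, seed = 2))
  mc_se <- stats::sd(d$dalys[, 1]) / sqrt(1e4)
  expect_lt(abs(mean(d$dalys[, 1]) - 0.0171754), 3 * mc_se)

  dall <- sample_draws(fixture_specs(), psa_config(n_sims = 1e4, seed = 2))
  mc_se <- stats::sd(dall$total) / sqrt(1e4)
  expect_lt(abs(mean(dall$total) - ANALYTIC_TOTAL_DALYS), 4 * mc_se)
})

test_that("predicted intervals are percentile-based with interpolation", {
  cfg <- psa_config(n_sims = 100, seed = 1)
  pi <- predicted_interval(1:100, cfg)
  expect_lte(pi[["low"]], 6); expect_gte(pi[["low"]], 1)
  expect_gte(pi[["high"]], 95); expect_lte(pi[["high"]], 100)
  expect_equal(unname(predicted_interval(rep(3.5, 40), cfg)), c(3.5, 3.5))
  set.seed(42)
  z <- stats::rnorm(1e5)
  pi <- predicted_interval(z, cfg)
  expect_equal(unname(pi), c(-1.645, 1.645), tolerance = 0.02)
})

test_that("psa_config validates its fields by name", {
  expect_error(psa_config(n_sims = 0), "n_sims")
  expect_error(psa_config(pi_percentiles = c(95, 5)), "pi_percentiles")
  expect_error(psa_config(risk_family = "gamma"))
})
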