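test_that("the ICER is the ratio of means with quadrant and undefined flags", {
  expect_equal(icer(100, 0.05)$icer, 2000)
  r <- icer(199, 0.119)
  expect_equal(r$icer, 1672.269, tolerance = 1e-6)
  expect_equal(r$quadrant, "NE")
  expect_false(r$undefined)

  u <- icer(199, 0)
  expect_true(u$undefined)
  expect_true(is.na(u$icer))

  expect_equal(icer(-50, 0.1)$quadrant, "SE")
  expect_equal(icer(50, -0.1)$quadrant, "NW")
})

test_that("net monetary benefit is lambda x effect minus cost", {
  expect_equal(nmb(1671, 199, 0.018), 30.078 - 199)
  expect_equal(nmb(1000, 100, 100 / 1000), 0)  # break-even identity
  expect_equal(nmb(0, 199, 0.5), -199)
})

test_that("break-even cost reduction and effect match the published magnitudes", {
  red <- required_cost_reduction(199, 0.018, 1671)
  expect_equal(red, 1 - 1671 * 0.018 / 199)
  expect_equal(round(100 * red), 85)
  expect_equal(required_cost_reduction(199, 199 / 1671, 1671), 0)
  expect_equal(required_cost_reduction(10, 0.5, 1671), 0)  # floored
  expect_error(required_cost_reduction(199, -0.01, 1671), "positive")

  eff <- required_effect(199, 1671, reference_effect = 0.018)
  expect_equal(eff$required_effect, 0.119, tolerance = 1e-3)
  expect_equal(eff$ratio, 0.1190903 / 0.018, tolerance = 1e-4)
  expect_equal(eff$fold_increase, eff$ratio - 1)
  expect_equal(required_effect(0, 1671)$required_effect, 0)
  expect_error(required_effect(199, 0), "lambda")
})

test_that("break-even answers invert back to the threshold exactly", {
  dc <- 199; eff <- 0.0174647; lam <- 1671
  red <- required_cost_reduction(dc, eff, lam)
  expect_equal(icer(dc * (1 - red), eff)$icer, lam)
  req <- required_effect(dc, lam)$required_effect
  expect_equal(icer(dc, req)$icer, lam)
})

test_that("the frontier reports both strategies and switches at the draws' ICER", {
  draws <- sample_draws(fixture_specs(), psa_config(n_sims = 4000, seed = 8))
  dc <- 199
  fr <- acceptability_frontier(draws, dc, lambda_grid = seq(0, 50000, 500))
  expect_equal(fr$p_intervention_ce + fr$p_usual_care_ce, rep(1, nrow(fr)))

  # expected-NMB crossover at lambda* = delta_cost / mean effect
  lam_star <- dc / mean(draws$total)
  expect_true(all(fr$optimal_strategy[fr$lambda < lam_star] == "usual_care"))
  expect_true(all(fr$optimal_strategy[fr$lambda > lam_star] == "intervention"))

  # decision consistency: icer <= lambda iff expected NMB >= 0
  for (lam in c(500, 5000, 20000)) {
    enmb <- mean(nmb(lam, dc, draws$total))
    expect_equal(icer(dc, mean(draws$total))$icer <= lam, enmb >= 0)
  }

  # at very large lambda the acceptance probability approaches P(effect > 0)
  far <- acceptability_frontier(draws, dc, lambda_grid = 1e9)
  expect_equal(far$p_intervention_ce, mean(draws$total > 0), tolerance = 0.01)
})

test_that("acceptance probability is non-decreasing in the threshold for
           normal and beta families", {
  for (fam in c("normal", "beta")) {
    draws <- sample_draws(fixture_specs(),
                          psa_config(n_sims = 4000, seed = 12, risk_family = fam))
    fr <- acceptability_frontier(draws, 199, seq(0, 50000, 1000))
    expect_true(all(diff(fr$p_intervention_ce) >= 0))
  }
})

test_that("ce_result assembles the incremental comparison coherently", {
  draws <- sample_draws(fixture_specs(), psa_config(n_sims = 5000, seed = 4))
  ce <- ce_result(draws, 199)
  expect_equal(ce$icer, 199 / mean(draws$total))
  expect_equal(ce$mean_delta_effect, mean(draws$total))
  expect_lt(ce$effect_pi[["low"]], ce$effect_pi[["high"]])
  expect_equal(ce$required_effect_at_upper$required_effect, 199 / 1671)
  expect_equal(length(ce$per_sim_icer), 5000)
  # per-sim ratios are inspection output; ratio of means is the estimate
  expect_false(isTRUE(all.equal(mean(ce$per_sim_icer), ce$icer)))
})
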