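test_that("bundled ledger reproduces the published funder totals and subtotals", {
  ledger <- load_cost_ledger(fixture_ledger_path())
  tot <- ledger_totals(ledger)
  expect_equal(tot$by_funder[["expertise_france"]], 163180)
  expect_equal(tot$by_funder[["global_fund"]], 396357)
  expect_equal(tot$grand_total, 559537)

  sub <- tot$by_funder_activity
  pick <- function(f, a) sub$amount_usd[sub$funder == f & sub$activity == a]
  expect_equal(pick("global_fund", "diagnosis_treatment"), 74671)
  expect_equal(pick("global_fund", "iec"), 319186)
  expect_equal(pick("expertise_france", "iec"), 160081)
  expect_equal(pick("global_fund", "program_management"), 2500)
  expect_equal(pick("expertise_france", "program_management"), 3099)
})

test_that("payer allocation divides shared costs evenly and conserves money", {
  one_line <- data.frame(funder = "global_fund", activity = "iec",
                         input_type = "consumables", amount_usd = 1000,
                         arm_scope = "both_arms")
  cfg <- costing_config(n_usual_care_denominator = 5,
                        n_intervention_denominator = 5)
  s <- allocate_payer_costs(one_line, cfg)
  expect_equal(s$per_person_usual_care, 100)
  expect_equal(s$per_person_intervention, 100)
  expect_equal(s$incremental_per_person, 0)

  # money conservation and linearity on a randomized ledger
  set.seed(404)
  for (i in 1:5) {
    k <- sample(2:6, 1)
    ledger <- data.frame(
      funder = sample(c("global_fund", "expertise_france"), k, replace = TRUE),
      activity = sample(c("iec", "diagnosis_treatment"), k, replace = TRUE),
      input_type = "consumables",
      amount_usd = round(stats::runif(k, 100, 9999), 2),
      arm_scope = sample(c("both_arms", "intervention_only"), k, replace = TRUE))
    n_u <- sample(50:300, 1); n_i <- sample(50:300, 1)
    cfg <- costing_config(n_usual_care_denominator = n_u,
                          n_intervention_denominator = n_i)
    s <- allocate_payer_costs(ledger, cfg)
    expect_equal(s$per_person_usual_care * n_u + s$per_person_intervention * n_i,
                 sum(ledger$amount_usd))
    doubled <- ledger; doubled$amount_usd <- 2 * doubled$amount_usd
    s2 <- allocate_payer_costs(doubled, cfg)
    expect_equal(s2$per_person_intervention, 2 * s$per_person_intervention)
    expect_equal(s2$total_usual_care, 2 * s$total_usual_care)
  }
})

test_that("per-person overrides pin the published incremental cost", {
  cfg <- costing_config(per_person_usual_care = 230,
                        per_person_intervention = 429)
  s <- allocate_payer_costs(load_cost_ledger(fixture_ledger_path()), cfg)
  expect_equal(s$incremental_per_person, 199)
  expect_equal(s$per_person_intervention - s$per_person_usual_care,
               s$incremental_per_person)
})

test_that("patient time savings follow the wage x time x contacts x rate chain", {
  cfg <- costing_config(time_with_outreach = 0.6, time_without_outreach = 2.2,
                        contacts_per_person = 2, hourly_wage = 6.75,
                        outreach_contact_rate_intervention = 1,
                        outreach_contact_rate_control = 0)
  expect_equal(patient_time_savings(cfg, "intervention"), 21.60)
  expect_equal(patient_time_savings(cfg, "control"), 0)
  cfg0 <- costing_config(hourly_wage = 0,
                         outreach_contact_rate_intervention = 1)
  expect_equal(patient_time_savings(cfg0, "intervention"), 0)
  # negative net time is allowed but warned about
  cfgneg <- costing_config(time_with_outreach = 3, time_without_outreach = 1,
                           outreach_contact_rate_intervention = 1)
  expect_warning(patient_time_savings(cfgneg, "intervention"), "negative")
})

test_that("combined perspective subtracts arm-level savings from payer costs", {
  payer <- allocate_payer_costs(
    load_cost_ledger(fixture_ledger_path()),
    costing_config(per_person_usual_care = 230, per_person_intervention = 429))

  # fixture rates differing by 0.185 reproduce the published $195
  cfg <- costing_config(outreach_contact_rate_intervention = 0.600,
                        outreach_contact_rate_control = 0.415)
  savings <- list(usual_care = patient_time_savings(cfg, "control"),
                  intervention = patient_time_savings(cfg, "intervention"))
  comb <- combined_perspective(payer, savings)
  expect_equal(comb$incremental_per_person, 195.004)
  expect_equal(round(comb$incremental_per_person), 195)

  # equal contact rates leave the incremental unchanged
  eq <- combined_perspective(payer, list(usual_care = 10, intervention = 10))
  expect_equal(eq$incremental_per_person, payer$incremental_per_person)

  # zero savings is the identity
  z <- combined_perspective(payer, list(usual_care = 0, intervention = 0))
  expect_equal(z$per_person_usual_care, payer$per_person_usual_care)
  expect_equal(z$per_person_intervention, payer$per_person_intervention)

  # perspective ordering when the intervention arm contacts outreach more
  expect_lte(comb$incremental_per_person, payer$incremental_per_person)
})
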