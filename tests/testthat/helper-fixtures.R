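# Study fixtures shared across tests: the five trial outcomes with their
# endline risks (percent, SD in pp) and disability weights (mean, SD).
fixture_specs <- function() {
  list(
    outcome_spec("hiv_testing", c(70.25, 5.93), c(68.93, 5.82), c(0.147, 0.085)),
    outcome_spec("sti_testing", c(29.17, 2.46), c(39.1, 3.3), c(0.006, 0.002)),
    outcome_spec("modern_contraceptive_use", c(41.47, 3.5), c(40.05, 3.38), c(0.014, 0.008)),
    outcome_spec("no_forced_drinking", c(66.36, 5.6), c(67.85, 5.73), c(0.123, 0.063)),
    outcome_spec("low_or_no_gbv", c(40.09, 3.39), c(48.23, 4.07), c(0.211, 0.109)))
}

fixture_config_path <- function() dalyeval_example("evaluation.yaml")
fixture_ledger_path <- function() dalyeval_example("cost_ledger.csv")

gbv_spec <- function() fixture_specs()[[5]]

# Printed point estimates the fixtures must reproduce.
FIXTURE_ARDS <- c(hiv_testing = -1.32, sti_testing = 9.93,
                  modern_contraceptive_use = -1.42,
                  no_forced_drinking = 1.49, low_or_no_gbv = 8.14)

# Analytic expectation of total DALYs averted from the point estimates:
# sum(ARD/100 * dw) over the five outcomes.
ANALYTIC_TOTAL_DALYS <- sum(FIXTURE_ARDS / 100 *
                            c(0.147, 0.006, 0.014, 0.123, 0.211))

write_temp_yaml <- function(lines) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
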