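#' Run manifest for reproducibility
#'
#' Collects everything needed to regenerate a result table bit-identically:
#' config file hash, seed, simulation count, distribution family, package
#' version, and a timestamp.
#'
#' @param config An `evaluation_config` (optional).
#' @param psa A [psa_config()] (optional).
#' @param extra Named list of additional metadata.
#' @return Named list.
#' @export
run_manifest <- function(config = NULL, psa = NULL, extra = list()) {
  m <- list(package = "dalyeval",
            version = as.character(utils::packageVersion("dalyeval")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(config)) {
    m$config_path <- config$path
    m$config_md5 <- unname(tools::md5sum(config$path))
  }
  if (!is.null(psa)) {
    m$seed <- psa$seed
    m$n_sims <- psa$n_sims
    m$risk_family <- psa$risk_family
    m$pi_percentiles <- psa$pi_percentiles
  }
  utils::modifyList(m, extra)
}

#' Per-outcome DALY summary across distribution families
#'
#' Builds the per-outcome, per-family table of mean DALYs averted with
#' predicted intervals, plus a totals row — the probabilistic model's
#' summary table. Values are carried at full precision; rounding is a
#' presentation concern.
#'
#' @param draws_by_family Named list of `draw_matrix` objects (names are
#'   the risk families).
#' @return A [result_table()] with columns `outcome`, then per family
#'   `<family>_mean`, `<family>_pi_low`, `<family>_pi_high`.
#' @export
daly_summary_table <- function(draws_by_family) {
  if (length(draws_by_family) == 0L || is.null(names(draws_by_family)))
    stop("'draws_by_family' must be a named list of draw matrices", call. = FALSE)
  families <- names(draws_by_family)
  labels <- colnames(draws_by_family[[1]]$dalys)
  for (fam in families) {
    d <- draws_by_family[[fam]]
    if (!inherits(d, "draw_matrix"))
      stop(sprintf("family '%s' is not a draw_matrix", fam), call. = FALSE)
    if (!identical(colnames(d$dalys), labels))
      stop("draw matrices must cover the same outcomes in the same order",
           call. = FALSE)
  }
  df <- data.frame(outcome = c(labels, "total"), stringsAsFactors = FALSE)
  for (fam in families) {
    d <- draws_by_family[[fam]]
    cols <- cbind(d$dalys, total = d$total)
    means <- colMeans(cols)
    pis <- apply(cols, 2, predicted_interval, config = d$config)
    df[[paste0(fam, "_mean")]] <- unname(means)
    df[[paste0(fam, "_pi_low")]] <- unname(pis[1, ])
    df[[paste0(fam, "_pi_high")]] <- unname(pis[2, ])
  }
  meta <- run_manifest(psa = draws_by_family[[1]]$config,
                       extra = list(families = families))
  result_table(df, meta)
}

#' Headline summary across all three analyses
#'
#' One table collecting the headline quantities: incremental cost per
#' perspective, mean total DALYs averted with its predicted interval,
#' ICERs, break-even values at the upper threshold, and budget-impact
#' totals. Stages not run are reported as `not_run` rows rather than
#' errors, so a partial pipeline still summarizes.
#'
#' @param cost_summaries List of `cost_summary` objects (may be empty).
#' @param ce_results List of `ce_result` objects (may be empty).
#' @param bia A `bia_result` or `NULL`.
#' @param manifest Optional metadata list from [run_manifest()].
#' @return A [result_table()] with columns `quantity`, `value`, `status`.
#' @export
headline_summary <- function(cost_summaries = list(), ce_results = list(),
                             bia = NULL, manifest = list()) {
  rows <- list()
  add <- function(quantity, value, status = "ok")
    rows[[length(rows) + 1L]] <<- data.frame(quantity = quantity,
                                             value = value, status = status,
                                             stringsAsFactors = FALSE)
  if (length(cost_summaries) == 0L)
    add("incremental_cost_per_person", NA_real_, "not_run")
  for (cs in cost_summaries)
    add(paste0("incremental_cost_per_person_", cs$perspective),
        cs$incremental_per_person)
  if (length(ce_results) == 0L) {
    add("mean_dalys_averted", NA_real_, "not_run")
    add("icer", NA_real_, "not_run")
  }
  for (ce in ce_results) {
    p <- ce$perspective
    add(paste0("mean_dalys_averted_", ce$risk_family), ce$mean_delta_effect)
    add(paste0("dalys_pi_low_", ce$risk_family), ce$effect_pi[["low"]])
    add(paste0("dalys_pi_high_", ce$risk_family), ce$effect_pi[["high"]])
    add(paste0("icer_", p), ce$icer,
        if (ce$icer_undefined) "undefined" else "ok")
    add(paste0("required_effect_at_upper_threshold_", p),
        ce$required_effect_at_upper$required_effect)
    add(paste0("required_cost_reduction_at_upper_threshold_", p),
        ce$required_cost_reduction_at_upper)
  }
  if (is.null(bia)) {
    add("bia_horizon_total", NA_real_, "not_run")
  } else {
    add("bia_horizon_total", bia$totals[["horizon"]])
    add("bia_final_coverage", max(bia$per_year$cumulative_coverage))
    add("bia_average_annual_cost", bia$average_annual_cost)
    add("bia_cost_per_person_year", bia$cost_pp_py)
  }
  result_table(do.call(rbind, rows), manifest)
}

# ---- pipeline runners (the CLI's back end) ----------------------------------

#' Run the cost analysis stage of a config
#'
#' Loads the ledger, allocates payer costs, applies patient time savings,
#' and returns both perspectives.
#'
#' @param config An `evaluation_config` with a `costing` section.
#' @return List with `ledger_totals`, `payer`, `payer_patient`, and a
#'   `table` ([result_table()]).
#' @export
run_cost_analysis <- function(config) {
  if (is.null(config$costing))
    stop("config has no 'costing' section", call. = FALSE)
  ledger <- if (!is.null(config$ledger_path)) load_cost_ledger(config$ledger_path)
            else data.frame(funder = character(), activity = character(),
                            input_type = character(), amount_usd = numeric(),
                            arm_scope = character())
  payer <- allocate_payer_costs(ledger, config$costing)
  savings <- list(
    usual_care = patient_time_savings(config$costing, "control"),
    intervention = patient_time_savings(config$costing, "intervention"))
  combined <- combined_perspective(payer, savings)
  df <- data.frame(
    perspective = c("payer", "payer_patient"),
    per_person_usual_care = c(payer$per_person_usual_care,
                              combined$per_person_usual_care),
    per_person_intervention = c(payer$per_person_intervention,
                                combined$per_person_intervention),
    incremental_per_person = c(payer$incremental_per_person,
                               combined$incremental_per_person),
    stringsAsFactors = FALSE)
  list(ledger_totals = if (nrow(ledger) > 0) ledger_totals(ledger) else NULL,
       payer = payer, payer_patient = combined, savings = savings,
       table = result_table(df, run_manifest(config,
                                             extra = list(stage = "cost"))))
}

#' Run the probabilistic cost-effectiveness stage of a config
#'
#' Samples the draw matrix, computes CE results for each perspective's
#' incremental cost, and evaluates the acceptability frontier.
#'
#' @param config An `evaluation_config` with `outcomes` and `psa`
#'   sections; `costing` supplies the incremental costs.
#' @param risk_family Optional override of the config's risk family.
#' @param n_sims,seed Optional overrides of the PSA settings.
#' @return List with `draws`, `ce` (per perspective), `frontier`,
#'   `daly_table`, `headline`.
#' @export
run_cea <- function(config, risk_family = NULL, n_sims = NULL, seed = NULL) {
  if (is.null(config$outcomes) || is.null(config$psa))
    stop("config needs 'outcomes' and 'psa' sections", call. = FALSE)
  psa <- config$psa
  if (!is.null(risk_family) || !is.null(n_sims) || !is.null(seed))
    psa <- psa_config(n_sims = n_sims %||% psa$n_sims,
                      seed = seed %||% psa$seed,
                      risk_family = risk_family %||% psa$risk_family,
                      pi_percentiles = psa$pi_percentiles)
  costs <- run_cost_analysis(config)
  draws <- sample_draws(config$outcomes, psa)
  thresholds <- config$cea$threshold_range %||% c(835, 1671)
  ce <- list(
    payer = ce_result(draws, costs$payer$incremental_per_person,
                      "payer", thresholds),
    payer_patient = ce_result(draws, costs$payer_patient$incremental_per_person,
                              "payer_patient", thresholds))
  grid <- seq(0, config$cea$lambda_grid_max %||% 50000,
              by = config$cea$lambda_grid_step %||% 250)
  frontier <- acceptability_frontier(draws,
                                     costs$payer$incremental_per_person, grid)
  daly_table <- daly_summary_table(stats::setNames(list(draws), psa$risk_family))
  headline <- headline_summary(list(costs$payer, costs$payer_patient), ce,
                               manifest = run_manifest(config, psa,
                                                       extra = list(stage = "cea")))
  list(draws = draws, costs = costs, ce = ce, frontier = frontier,
       daly_table = daly_table, headline = headline)
}

#' Run the budget impact stage of a config
#'
#' @param config An `evaluation_config` with a `bia` section.
#' @return List with `schedule`, `result`, `workforce`, and `table`.
#' @export
run_bia <- function(config) {
  if (is.null(config$bia))
    stop("config has no 'bia' section", call. = FALSE)
  schedule <- scale_up_schedule(config$bia)
  result <- project_costs(schedule, config$bia)
  workforce <- outreach_workforce(schedule, config$bia)
  df <- cbind(result$per_year, outreach_workers = workforce)
  list(schedule = schedule, result = result, workforce = workforce,
       table = result_table(df, run_manifest(config,
                                             extra = list(stage = "bia",
                                                          shares = as.list(result$shares)))))
}
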