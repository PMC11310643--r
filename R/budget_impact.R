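#' Budget impact configuration
#'
#' Parameters for projecting the undiscounted financial cost of scaling a
#' messaging-plus-outreach programme to a target population over a
#' multi-year horizon. Defaults describe a national scale-up to the
#' estimated 50,000 female entertainment workers in Cambodia: 6,958 new
#' enrollees per year for 5 years (~70% final coverage), US $2.66 per
#' person per year for messaging and US $9.54 for outreach workers, with
#' any fixed startup cost (platform development, testing) applied in year
#' one only.
#'
#' @param total_population Target population size.
#' @param annual_new_enrollees New enrollees added each year.
#' @param years Horizon in years.
#' @param messaging_cost_pp_py US $ per covered person per year, messaging.
#' @param outreach_cost_pp_py US $ per covered person per year, outreach
#'   workers (salaries, training, communication, travel).
#' @param fews_per_outreach_worker Caseload: persons served per outreach
#'   worker (informational; costs use the per-person rate).
#' @param startup_cost One-off US $ cost applied in year 1.
#' @return An object of class `bia_config`.
#' @export
bia_config <- function(total_population = 50000,
                       annual_new_enrollees = 6958,
                       years = 5,
                       messaging_cost_pp_py = 2.66,
                       outreach_cost_pp_py = 9.54,
                       fews_per_outreach_worker = 280,
                       startup_cost = 0) {
  if (total_population < 1 || years < 1 || fews_per_outreach_worker < 1)
    stop("population, years and caseload must be >= 1", call. = FALSE)
  if (annual_new_enrollees < 0)
    stop("'annual_new_enrollees' must be non-negative", call. = FALSE)
  if (messaging_cost_pp_py < 0 || outreach_cost_pp_py < 0 || startup_cost < 0)
    stop("costs must be non-negative", call. = FALSE)
  if (years * annual_new_enrollees > total_population)
    stop("scale-up schedule exceeds the target population", call. = FALSE)
  structure(list(total_population = total_population,
                 annual_new_enrollees = annual_new_enrollees,
                 years = as.integer(years),
                 messaging_cost_pp_py = messaging_cost_pp_py,
                 outreach_cost_pp_py = outreach_cost_pp_py,
                 fews_per_outreach_worker = fews_per_outreach_worker,
                 startup_cost = startup_cost),
            class = "bia_config")
}

#' Linear scale-up schedule
#'
#' A constant number of new enrollees each year; coverage is cumulative
#' and non-decreasing.
#'
#' @param config A [bia_config()].
#' @return Data frame with `year`, `new_enrollees`, `cumulative_coverage`,
#'   and `coverage_fraction` (of the target population).
#' @export
scale_up_schedule <- function(config = bia_config()) {
  stopifnot(inherits(config, "bia_config"))
  year <- seq_len(config$years)
  cum <- config$annual_new_enrollees * year
  data.frame(year = year,
             new_enrollees = rep(config$annual_new_enrollees, config$years),
             cumulative_coverage = cum,
             coverage_fraction = cum / config$total_population)
}

#' Project scale-up costs over the horizon
#'
#' Variable costs accrue on *cumulative* coverage each year (everyone
#' enrolled so far keeps receiving messages and outreach), so the annual
#' cost is `startup * [year == 1] + cumulative * (messaging + outreach)`
#' per-person rates. No discounting is applied: the budget impact is the
#' undiscounted financial cost a payer must budget.
#'
#' @param schedule Output of [scale_up_schedule()].
#' @param config A [bia_config()].
#' @return An object of class `bia_result`: a list with the `per_year`
#'   data frame (enrollment, per-category and total costs), `totals`
#'   (per-category and horizon totals), `shares` (category shares of the
#'   horizon total), `average_annual_cost`, `cost_pp_py` (horizon total
#'   divided by the final cumulative coverage — the average cost of
#'   covering one person for the horizon, per year), and
#'   `cost_per_person_year` (horizon total over person-years of coverage).
#' @export
project_costs <- function(schedule, config = bia_config()) {
  stopifnot(inherits(config, "bia_config"))
  cum <- schedule$cumulative_coverage
  messaging <- cum * config$messaging_cost_pp_py
  outreach <- cum * config$outreach_cost_pp_py
  startup <- ifelse(schedule$year == 1, config$startup_cost, 0)
  year_total <- startup + messaging + outreach
  per_year <- cbind(schedule,
                    data.frame(startup_cost = startup,
                               messaging_cost = messaging,
                               outreach_cost = outreach,
                               year_total = year_total))
  totals <- c(startup = sum(startup), messaging = sum(messaging),
              outreach = sum(outreach), horizon = sum(year_total))
  shares <- totals[c("startup", "messaging", "outreach")] / totals[["horizon"]]
  person_years <- sum(cum)
  structure(list(per_year = per_year,
                 totals = totals,
                 shares = shares,
                 average_annual_cost = totals[["horizon"]] / config$years,
                 person_years = person_years,
                 cost_pp_py = totals[["horizon"]] / max(cum),
                 cost_per_person_year = totals[["horizon"]] / person_years,
                 config = config),
            class = "bia_result")
}

#' @export
print.bia_result <- function(x, ...) {
  cat(sprintf("<bia_result> %d-year scale-up to %s people (%.0f%% coverage)\n",
              x$config$years,
              format(max(x$per_year$cumulative_coverage), big.mark = ","),
              100 * max(x$per_year$coverage_fraction)))
  cat(sprintf("  horizon total $%s (startup %.0f%%, messaging %.0f%%, outreach %.0f%%)\n",
              format(round(x$totals[["horizon"]]), big.mark = ","),
              100 * x$shares[["startup"]], 100 * x$shares[["messaging"]],
              100 * x$shares[["outreach"]]))
  cat(sprintf("  average annual $%s; $%.0f per covered person per year\n",
              format(round(x$average_annual_cost), big.mark = ","), x$cost_pp_py))
  invisible(x)
}

#' Outreach workforce implied by the schedule
#'
#' Headcount needed each year at the configured caseload,
#' `ceiling(cumulative / caseload)`. Informational: costs are modelled per
#' covered person, not per worker.
#'
#' @param schedule Output of [scale_up_schedule()].
#' @param config A [bia_config()].
#' @return Integer vector of per-year worker counts.
#' @export
outreach_workforce <- function(schedule, config = bia_config()) {
  stopifnot(inherits(config, "bia_config"))
  as.integer(ceiling(schedule$cumulative_coverage / config$fews_per_outreach_worker))
}
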