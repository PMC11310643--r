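ACTIVITY_LEVELS <- c("diagnosis_treatment", "iec", "program_management")
INPUT_TYPE_LEVELS <- c("consumables", "personnel")
ARM_SCOPE_LEVELS <- c("both_arms", "intervention_only")
FUNDER_LEVELS <- c("expertise_france", "global_fund")

#' Costing configuration
#'
#' Denominators and patient-time parameters for the cost analysis. The
#' per-person overrides exist because published per-person costs are
#' sometimes primary inputs (their denominators unpublished); when
#' supplied they take precedence over ledger allocation.
#'
#' @param n_usual_care_denominator,n_intervention_denominator Participant
#'   counts over which costs are spread. Shared (both-arms) costs are
#'   divided evenly over their sum; intervention-only costs over the
#'   intervention denominator.
#' @param per_person_usual_care,per_person_intervention Optional US $
#'   per-person overrides.
#' @param time_with_outreach,time_without_outreach Hours to access health
#'   services with and without an outreach worker's help.
#' @param contacts_per_person Outreach contacts per participant over the
#'   analytic horizon.
#' @param hourly_wage US $ per hour used to value participant time.
#' @param outreach_contact_rate_intervention,outreach_contact_rate_control
#'   Proportion of each arm that contacted an outreach worker.
#' @return An object of class `costing_config`.
#' @export
costing_config <- function(n_usual_care_denominator = NULL,
                           n_intervention_denominator = NULL,
                           per_person_usual_care = NULL,
                           per_person_intervention = NULL,
                           time_with_outreach = 0.6,
                           time_without_outreach = 2.2,
                           contacts_per_person = 2,
                           hourly_wage = 6.75,
                           outreach_contact_rate_intervention = 0,
                           outreach_contact_rate_control = 0) {
  for (nm in c("n_usual_care_denominator", "n_intervention_denominator")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || v < 1))
      stop(sprintf("'%s' must be >= 1", nm), call. = FALSE)
  }
  if (time_with_outreach < 0 || time_without_outreach < 0)
    stop("times must be non-negative hours", call. = FALSE)
  for (nm in c("outreach_contact_rate_intervention", "outreach_contact_rate_control")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(sprintf("'%s' must be in [0, 1]", nm), call. = FALSE)
  }
  structure(list(n_usual_care_denominator = n_usual_care_denominator,
                 n_intervention_denominator = n_intervention_denominator,
                 per_person_usual_care = per_person_usual_care,
                 per_person_intervention = per_person_intervention,
                 time_with_outreach = time_with_outreach,
                 time_without_outreach = time_without_outreach,
                 contacts_per_person = contacts_per_person,
                 hourly_wage = hourly_wage,
                 outreach_contact_rate_intervention = outreach_contact_rate_intervention,
                 outreach_contact_rate_control = outreach_contact_rate_control),
            class = "costing_config")
}

new_cost_summary <- function(perspective, pp_u, pp_i, total_u = NA_real_,
                             total_i = NA_real_) {
  structure(list(perspective = perspective,
                 total_usual_care = total_u,
                 total_intervention = total_i,
                 per_person_usual_care = pp_u,
                 per_person_intervention = pp_i,
                 incremental_per_person = pp_i - pp_u),
            class = "cost_summary")
}

#' @export
print.cost_summary <- function(x, ...) {
  cat(sprintf("<cost_summary> %s perspective\n", x$perspective))
  cat(sprintf("  per person: usual care $%.2f, intervention $%.2f, incremental $%.2f\n",
              x$per_person_usual_care, x$per_person_intervention,
              x$incremental_per_person))
  if (!is.na(x$total_usual_care))
    cat(sprintf("  totals    : usual care $%.0f, intervention $%.0f\n",
                x$total_usual_care, x$total_intervention))
  invisible(x)
}

#' Allocate ledger costs to arms (payer perspective)
#'
#' Implements top-down cost allocation: expenditure lines flagged
#' `both_arms` (the usual-care package available to everyone) are divided
#' evenly among all participants in both arms; `intervention_only` lines
#' are spread over intervention-arm participants alone. The intervention
#' arm's per-person cost is therefore the shared per-person amount plus its
#' exclusive per-person amount. Per-person overrides in the config bypass
#' the allocation entirely.
#'
#' @param ledger A cost ledger data frame from [load_cost_ledger()].
#' @param config A [costing_config()].
#' @return A `cost_summary` (payer perspective).
#' @export
allocate_payer_costs <- function(ledger, config) {
  stopifnot(inherits(config, "costing_config"))
  ov_u <- config$per_person_usual_care
  ov_i <- config$per_person_intervention
  n_u <- config$n_usual_care_denominator
  n_i <- config$n_intervention_denominator
  if (!is.null(ov_u) && !is.null(ov_i)) {
    total_u <- if (!is.null(n_u)) ov_u * n_u else NA_real_
    total_i <- if (!is.null(n_i)) ov_i * n_i else NA_real_
    return(new_cost_summary("payer", ov_u, ov_i, total_u, total_i))
  }
  if (is.null(n_u) || is.null(n_i))
    stop("denominators are required unless both per-person overrides are set",
         call. = FALSE)
  shared <- sum(ledger$amount_usd[ledger$arm_scope == "both_arms"])
  exclusive <- sum(ledger$amount_usd[ledger$arm_scope == "intervention_only"])
  pp_shared <- shared / (n_u + n_i)
  pp_u <- pp_shared
  pp_i <- pp_shared + exclusive / n_i
  new_cost_summary("payer", pp_u, pp_i, pp_u * n_u, pp_i * n_i)
}

#' Per-person patient time savings from outreach contact
#'
#' Participants who reach services through an outreach worker spend less
#' time doing so; the saving per contact is the time difference valued at
#' the participants' earnings rate, accrued over the expected contacts and
#' scaled by the arm's outreach-contact rate.
#'
#' @param config A [costing_config()].
#' @param arm `"intervention"` or `"control"`.
#' @return US $ per person.
#' @examples
#' cfg <- costing_config(outreach_contact_rate_intervention = 1)
#' patient_time_savings(cfg, "intervention")  # 6.75 * 1.6 h * 2 contacts = 21.60
#' @export
patient_time_savings <- function(config, arm = c("intervention", "control")) {
  stopifnot(inherits(config, "costing_config"))
  arm <- match.arg(arm)
  dt <- config$time_without_outreach - config$time_with_outreach
  if (dt < 0)
    warning("time without outreach is shorter than with outreach; savings are negative")
  rate <- switch(arm,
                 intervention = config$outreach_contact_rate_intervention,
                 control = config$outreach_contact_rate_control)
  config$hourly_wage * dt * config$contacts_per_person * rate
}

#' Combined payer and patient perspective
#'
#' Subtracts each arm's per-person patient time savings from its payer
#' per-person cost and recomputes the incremental cost. When the
#' intervention arm's outreach-contact rate exceeds the control arm's, the
#' combined-perspective incremental cost is below the payer one.
#'
#' @param payer_summary A payer-perspective `cost_summary`.
#' @param savings_by_arm Named list or vector with elements `usual_care`
#'   and `intervention`: US $ savings per person. Usually built from
#'   [patient_time_savings()].
#' @return A `cost_summary` with perspective `"payer_patient"`.
#' @export
combined_perspective <- function(payer_summary, savings_by_arm) {
  stopifnot(inherits(payer_summary, "cost_summary"))
  s_u <- savings_by_arm[["usual_care"]]
  s_i <- savings_by_arm[["intervention"]]
  pp_u <- payer_summary$per_person_usual_care - s_u
  pp_i <- payer_summary$per_person_intervention - s_i
  new_cost_summary("payer_patient", pp_u, pp_i,
                   payer_summary$total_usual_care -
                     s_u * (payer_summary$total_usual_care /
                              payer_summary$per_person_usual_care),
                   payer_summary$total_intervention -
                     s_i * (payer_summary$total_intervention /
                              payer_summary$per_person_intervention))
}

#' Per-funder and per-activity ledger totals
#'
#' @param ledger A cost ledger data frame.
#' @return A list with `by_funder` (named totals), `by_funder_activity`
#'   (data frame of subtotals), and `grand_total`.
#' @export
ledger_totals <- function(ledger) {
  by_funder <- tapply(ledger$amount_usd, ledger$funder, sum, default = 0)
  sub <- if (nrow(ledger) == 0L)
    data.frame(funder = character(), activity = character(),
               amount_usd = numeric())
  else stats::aggregate(amount_usd ~ funder + activity, data = ledger, FUN = sum)
  list(by_funder = by_funder,
       by_funder_activity = sub,
       grand_total = sum(ledger$amount_usd))
}
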