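#' Incremental cost-effectiveness ratio
#'
#' The ratio of the incremental cost to the mean incremental effect — a
#' ratio of expected values, not the mean of per-simulation ratios, which
#' is undefined and unstable whenever the effect distribution crosses zero.
#' The result carries the cost-effectiveness-plane quadrant (NE/SE/NW/SW)
#' since a negative ICER is uninterpretable without it, and an `undefined`
#' flag when the mean effect is numerically zero.
#'
#' @param delta_cost Incremental cost per person (US $).
#' @param mean_delta_effect Mean incremental effect (DALYs averted per
#'   person).
#' @param tol Magnitude below which the mean effect counts as zero.
#' @return A list with `icer` (US $ per DALY averted; `NA` when
#'   undefined), `undefined`, and `quadrant`.
#' @examples
#' icer(199, 0.119)  # at the break-even effect the ICER is ~1672 $/DALY
#' @export
icer <- function(delta_cost, mean_delta_effect, tol = .Machine$double.eps^0.5) {
  undefined <- abs(mean_delta_effect) < tol
  quadrant <- paste0(if (delta_cost >= 0) "N" else "S",
                     if (mean_delta_effect >= 0) "E" else "W")
  list(icer = if (undefined) NA_real_ else delta_cost / mean_delta_effect,
       undefined = undefined, quadrant = quadrant)
}

#' Net monetary benefit
#'
#' `lambda * delta_effect - delta_cost`: the incremental effect valued at a
#' willingness-to-pay threshold, minus the incremental cost. Positive NMB
#' at a threshold means the intervention is cost-effective there.
#'
#' @param lambda Willingness-to-pay threshold (US $ per DALY averted).
#' @param delta_cost Incremental cost (US $).
#' @param delta_effect Incremental effect (DALYs averted); may be a vector
#'   of per-simulation draws.
#' @return US $, same length as `delta_effect`.
#' @export
nmb <- function(lambda, delta_cost, delta_effect) {
  lambda * delta_effect - delta_cost
}

#' Cost-effectiveness acceptability frontier
#'
#' For each threshold on a grid, computes the probability that each of the
#' two strategies (intervention vs. usual care) is cost-effective — the
#' share of simulations in which it has the higher net monetary benefit,
#' with usual care as the zero-NMB reference — and identifies the optimal
#' strategy as the one with the higher *expected* NMB. The frontier is the
#' optimal strategy's probability; the switch point where the optimum
#' changes equals the ICER of the draws.
#'
#' @param draws A `draw_matrix` from [sample_draws()], or a numeric vector
#'   of per-simulation incremental effects.
#' @param delta_cost Incremental cost per person (US $).
#' @param lambda_grid Thresholds (US $ per DALY averted). The default grid
#'   0-50,000 in $250 steps spans the range over which decision reversals
#'   are plausible for this intervention class.
#' @return A data frame with columns `lambda`, `p_intervention_ce`,
#'   `p_usual_care_ce`, `optimal_strategy`, `p_optimal`.
#' @export
acceptability_frontier <- function(draws, delta_cost,
                                   lambda_grid = seq(0, 50000, by = 250)) {
  delta_effect <- if (inherits(draws, "draw_matrix")) draws$total else as.numeric(draws)
  if (length(delta_effect) == 0L || length(lambda_grid) == 0L)
    stop("draws and lambda_grid must be nonempty", call. = FALSE)
  mean_effect <- mean(delta_effect)
  rows <- lapply(lambda_grid, function(lam) {
    b <- nmb(lam, delta_cost, delta_effect)
    p_int <- mean(b > 0)
    optimal <- if (mean(b) > 0) "intervention" else "usual_care"
    data.frame(lambda = lam,
               p_intervention_ce = p_int,
               p_usual_care_ce = 1 - p_int,
               optimal_strategy = optimal,
               p_optimal = if (optimal == "intervention") p_int else 1 - p_int,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cost reduction needed to reach a threshold
#'
#' The fraction by which the incremental cost must fall for the ICER to
#' equal the willingness-to-pay threshold at the current mean effect:
#' `1 - lambda * mean_delta_effect / delta_cost`, floored at zero (no
#' reduction is needed if the intervention is already cost-effective).
#'
#' @param delta_cost Incremental cost per person (US $); must be positive.
#' @param mean_delta_effect Mean DALYs averted; must be positive.
#' @param lambda Threshold (US $ per DALY averted).
#' @return Fraction in \[0, 1\].
#' @export
required_cost_reduction <- function(delta_cost, mean_delta_effect, lambda) {
  if (mean_delta_effect <= 0)
    stop("break-even cost reduction requires a positive mean effect", call. = FALSE)
  if (delta_cost <= 0) return(0)
  max(0, 1 - lambda * mean_delta_effect / delta_cost)
}

#' Effect needed to reach a threshold
#'
#' The mean DALYs averted at which the ICER equals the threshold:
#' `delta_cost / lambda`. When a reference effect is supplied, the gap is
#' also reported as a multiplier — both as the plain ratio
#' (required/reference) and as ratio minus one ("times higher" in the
#' fold-increase sense); the two conventions are frequently conflated in
#' prose, so both are emitted, labelled.
#'
#' @param delta_cost Incremental cost per person (US $).
#' @param lambda Threshold (US $ per DALY averted); must be positive.
#' @param reference_effect Optional current mean DALYs averted.
#' @return A list with `required_effect` and, when a reference is given,
#'   `ratio` and `fold_increase` (= ratio - 1).
#' @export
required_effect <- function(delta_cost, lambda, reference_effect = NULL) {
  if (lambda <= 0) stop("'lambda' must be positive", call. = FALSE)
  req <- delta_cost / lambda
  out <- list(required_effect = req)
  if (!is.null(reference_effect)) {
    out$ratio <- req / reference_effect
    out$fold_increase <- req / reference_effect - 1
  }
  out
}

#' Summarize a cost-effectiveness comparison
#'
#' Combines an incremental cost with simulated incremental effects into a
#' single result: the ICER (ratio of means), the predicted interval of the
#' effect, per-simulation ICERs (for inspection only), and break-even
#' diagnostics against a threshold range.
#'
#' @param draws A `draw_matrix` from [sample_draws()].
#' @param delta_cost Incremental cost per person (US $).
#' @param perspective Label, e.g. `"payer"` or `"payer_patient"`.
#' @param threshold_range Length-2 thresholds (US $/DALY); the default is
#'   50%-100% of Cambodia's 2019 per-capita GDP.
#' @return An object of class `ce_result`.
#' @export
ce_result <- function(draws, delta_cost, perspective = "payer",
                      threshold_range = c(835, 1671)) {
  stopifnot(inherits(draws, "draw_matrix"))
  eff <- draws$total
  mean_eff <- mean(eff)
  ic <- icer(delta_cost, mean_eff)
  upper <- max(threshold_range)
  structure(list(
    perspective = perspective,
    delta_cost_per_person = delta_cost,
    mean_delta_effect = mean_eff,
    effect_pi = predicted_interval(eff, draws$config),
    icer = ic$icer,
    icer_undefined = ic$undefined,
    icer_quadrant = ic$quadrant,
    per_sim_icer = ifelse(eff == 0, NA_real_, delta_cost / eff),
    threshold_range = threshold_range,
    required_effect_at_upper =
      required_effect(delta_cost, upper, reference_effect = mean_eff),
    required_cost_reduction_at_upper =
      if (mean_eff > 0) required_cost_reduction(delta_cost, mean_eff, upper) else NA_real_,
    n_sims = length(eff),
    seed = draws$config$seed,
    risk_family = draws$config$risk_family), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("<ce_result> %s perspective (%s risks, %d sims, seed %d)\n",
              x$perspective, x$risk_family, x$n_sims, x$seed))
  cat(sprintf("  incremental cost  : $%.2f per person\n", x$delta_cost_per_person))
  cat(sprintf("  mean DALYs averted: %.4f  PI [%.4f, %.4f]\n",
              x$mean_delta_effect, x$effect_pi[1], x$effect_pi[2]))
  if (x$icer_undefined) cat("  ICER: undefined (mean effect ~ 0)\n")
  else cat(sprintf("  ICER: $%.0f per DALY averted (%s quadrant)\n",
                   x$icer, x$icer_quadrant))
  cat(sprintf("  at $%d/DALY: need effect %.3f (x%.2f) or cost -%.0f%%\n",
              max(x$threshold_range),
              x$required_effect_at_upper$required_effect,
              x$required_effect_at_upper$ratio,
              100 * x$required_cost_reduction_at_upper))
  invisible(x)
}
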