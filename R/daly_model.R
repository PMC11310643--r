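#' Define a trial outcome for the DALY model
#'
#' An outcome spec bundles the arm-level endline risks of one binary trial
#' outcome (percent scale, with standard deviations in percentage points)
#' together with the disability weight its health state maps to. All five
#' bundled outcomes are coded so that a higher endline "risk" is the
#' favourable state (tested, used contraception, no forced drinking, low or
#' no gender-based violence); the disability weight then measures the burden
#' avoided when the favourable state occurs.
#'
#' @param name Outcome label.
#' @param risk_control,risk_intervention Numeric length-2 vectors
#'   `c(mean, sd)` on the percent scale (0-100; sd in percentage points).
#' @param dw Numeric length-2 vector `c(mean, sd)`: the dimensionless
#'   disability weight in (0, 1) and its standard deviation.
#'
#' @return An object of class `outcome_spec`.
#' @examples
#' gbv <- outcome_spec("gender_based_violence",
#'                     risk_control = c(40.09, 3.39),
#'                     risk_intervention = c(48.23, 4.07),
#'                     dw = c(0.211, 0.109))
#' ard(gbv)
#' @export
outcome_spec <- function(name, risk_control, risk_intervention, dw) {
  stopifnot(is.character(name), length(name) == 1L)
  check_mean_sd <- function(x, what, lo, hi) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x))
      stop(sprintf("'%s' must be a numeric c(mean, sd) pair", what), call. = FALSE)
    if (x[1] < lo || x[1] > hi)
      stop(sprintf("'%s' mean %g outside [%g, %g]", what, x[1], lo, hi), call. = FALSE)
    if (x[2] < 0)
      stop(sprintf("'%s' sd must be non-negative", what), call. = FALSE)
  }
  check_mean_sd(risk_control, "risk_control", 0, 100)
  check_mean_sd(risk_intervention, "risk_intervention", 0, 100)
  check_mean_sd(dw, "dw", 0, 1)
  if (dw[1] <= 0 || dw[1] >= 1)
    stop("disability weight mean must lie strictly in (0, 1)", call. = FALSE)
  if (dw[2]^2 >= dw[1] * (1 - dw[1]))
    stop("disability weight sd^2 must be < mean*(1-mean) for a beta distribution",
         call. = FALSE)
  structure(
    list(name = name,
         risk_control = c(mean = unname(risk_control[1]), sd = unname(risk_control[2])),
         risk_intervention = c(mean = unname(risk_intervention[1]), sd = unname(risk_intervention[2])),
         dw = c(mean = unname(dw[1]), sd = unname(dw[2]))),
    class = "outcome_spec")
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat(sprintf("<outcome_spec> %s\n", x$name))
  cat(sprintf("  control risk      %6.2f%% (SD %.2f pp)\n",
              x$risk_control["mean"], x$risk_control["sd"]))
  cat(sprintf("  intervention risk %6.2f%% (SD %.2f pp)\n",
              x$risk_intervention["mean"], x$risk_intervention["sd"]))
  cat(sprintf("  disability weight %6.3f (SD %.3f)\n",
              x$dw["mean"], x$dw["sd"]))
  cat(sprintf("  ARD %+.2f pp\n", ard(x)))
  invisible(x)
}

#' Absolute risk difference of an outcome
#'
#' Intervention-arm endline risk minus control-arm endline risk, in
#' percentage points. Negative values flag outcomes on which the
#' intervention underperformed usual care.
#'
#' @param spec An [outcome_spec()].
#' @return Numeric scalar, percentage points.
#' @export
ard <- function(spec) {
  stopifnot(inherits(spec, "outcome_spec"))
  unname(spec$risk_intervention["mean"] - spec$risk_control["mean"])
}

#' Disability-weight adjustment for test-and-treat cascades
#'
#' Raw disability weights taken from burden-of-disease sources describe the
#' health state itself; for screening outcomes (HIV/STI testing) the weight
#' attached to a testing outcome should reflect how likely a tested person
#' is to have the condition and to be treated after a positive result. The
#' bundled weights are treated as already adjusted; this generic hook
#' supports users supplying raw weights. `mode = "none"` (default) is the
#' identity; `mode = "multiplicative"` scales the weight by
#' `prevalence * p_treated_after_positive`.
#'
#' @param dw_mean Disability-weight mean in (0, 1).
#' @param adjustment A list with `mode` ("none" or "multiplicative") and,
#'   for the multiplicative mode, proportions `prevalence` and
#'   `p_treated_after_positive` in \[0, 1\].
#' @return Adjusted disability-weight mean.
#' @export
adjust_dw <- function(dw_mean, adjustment = list(mode = "none")) {
  mode <- match.arg(adjustment$mode, c("none", "multiplicative"))
  if (mode == "none") return(dw_mean)
  prev <- adjustment$prevalence
  p_tx <- adjustment$p_treated_after_positive
  for (p in list(prev, p_tx))
    if (is.null(p) || !is.numeric(p) || p < 0 || p > 1)
      stop("multiplicative adjustment needs 'prevalence' and 'p_treated_after_positive' in [0, 1]",
           call. = FALSE)
  dw_mean * prev * p_tx
}

#' DALYs averted by one outcome over a one-year horizon
#'
#' With a 1-year analytic horizon and no mortality pathway, the DALYs
#' attached to a health state equal its disability weight, so the DALYs
#' averted per person are the absolute risk difference (as a proportion)
#' times the disability weight times one year. The sign follows the ARD:
#' outcomes on which the intervention underperforms contribute negatively.
#'
#' @param ard Absolute risk difference in percentage points.
#' @param dw Disability weight (dimensionless).
#' @return DALYs averted per person per year.
#' @export
dalys_averted <- function(ard, dw) {
  (ard / 100) * dw
}

#' Total DALYs averted across outcomes
#'
#' Arithmetic sum of the per-outcome DALYs averted; outcomes are treated as
#' independent additive contributions.
#'
#' @param per_outcome Numeric vector of per-outcome DALYs averted.
#' @return Numeric scalar.
#' @export
total_dalys_averted <- function(per_outcome) {
  if (length(per_outcome) == 0L)
    stop("'per_outcome' must be nonempty", call. = FALSE)
  sum(per_outcome)
}
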