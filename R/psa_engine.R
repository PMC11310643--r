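#' Probabilistic sensitivity analysis settings
#'
#' @param n_sims Number of Monte Carlo simulations (default 10,000, the
#'   standard resolution for trial-based probabilistic models).
#' @param seed Integer seed for the single random generator driving all
#'   draws.
#' @param risk_family Distribution assigned to each arm's endline risk:
#'   `"normal"` (base case), `"beta"`, or `"uniform"`. Disability weights
#'   are always drawn from moment-matched beta distributions.
#' @param pi_percentiles Percentile pair (0-100) defining the predicted
#'   interval; the default `c(5, 95)` is the 5th-95th percentile range.
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_sims = 10000L, seed = 1L,
                       risk_family = c("normal", "beta", "uniform"),
                       pi_percentiles = c(5, 95)) {
  risk_family <- match.arg(risk_family)
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L)
    stop("'n_sims' must be a positive integer", call. = FALSE)
  if (length(pi_percentiles) != 2L || anyNA(pi_percentiles) ||
      pi_percentiles[1] >= pi_percentiles[2] ||
      pi_percentiles[1] <= 0 || pi_percentiles[2] >= 100)
    stop("'pi_percentiles' must be an ordered pair within (0, 100)", call. = FALSE)
  structure(list(n_sims = n_sims, seed = as.integer(seed),
                 risk_family = risk_family,
                 pi_percentiles = as.numeric(pi_percentiles)),
            class = "psa_config")
}

#' Moment-matched beta shape parameters
#'
#' Solves the beta distribution's first two moment equations for the shape
#' pair: with `k = mean*(1-mean)/sd^2 - 1`, `alpha = mean*k` and
#' `beta = (1-mean)*k`. The returned shapes reproduce the input mean and sd
#' exactly.
#'
#' @param mean Mean on the proportion scale, strictly in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean*(1-mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @examples
#' beta_from_moments(0.5, sqrt(1 / 12))  # Beta(1, 1), the uniform
#' @export
beta_from_moments <- function(mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  if (mean <= 0 || mean >= 1)
    stop("beta moment matching needs 0 < mean < 1 (got ", mean, ")", call. = FALSE)
  if (sd <= 0)
    stop("beta moment matching needs sd > 0", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop(sprintf("infeasible beta moments: sd^2 = %.5g >= mean*(1-mean) = %.5g",
                 sd^2, mean * (1 - mean)), call. = FALSE)
  k <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Moment-matched uniform bounds
#'
#' Bounds `mean +/- sqrt(3)*sd`, the unique uniform distribution with the
#' given mean and standard deviation.
#'
#' @param mean,sd Target mean and standard deviation (`sd >= 0`).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
uniform_from_moments <- function(mean, sd) {
  mean <- unname(mean); sd <- unname(sd)
  if (sd < 0) stop("'sd' must be non-negative", call. = FALSE)
  h <- sqrt(3) * sd
  c(lower = mean - h, upper = mean + h)
}

# One column of arm-risk draws on the percent scale; normal draws are
# deliberately not truncated to [0, 100] (truncation would bias the moments
# away from the published summaries).
draw_risk <- function(n, mean_pct, sd_pct, family) {
  if (sd_pct == 0) return(rep(mean_pct, n))
  switch(family,
    normal = stats::rnorm(n, mean_pct, sd_pct),
    beta = {
      sh <- beta_from_moments(mean_pct / 100, sd_pct / 100)
      100 * stats::rbeta(n, sh["alpha"], sh["beta"])
    },
    uniform = {
      b <- uniform_from_moments(mean_pct, sd_pct)
      stats::runif(n, b["lower"], b["upper"])
    })
}

draw_dw <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  sh <- beta_from_moments(mean, sd)
  stats::rbeta(n, sh["alpha"], sh["beta"])
}

#' Monte Carlo draws of risks, ARDs, disability weights and DALYs averted
#'
#' For each simulation and outcome, draws the control and intervention
#' endline risks independently from the configured family (moment-matched
#' to each arm's mean/SD), forms the absolute risk difference, draws the
#' disability weight from its moment-matched beta, and computes the DALYs
#' averted as `(ARD/100) * dw`. All draws come from a single seeded
#' generator in a fixed, documented order — outcome-major: for each outcome
#' in turn, its control risks, then its intervention risks, then its
#' disability weights — so runs are bit-reproducible at a fixed seed.
#'
#' Draws across outcomes, between arms, and between risks and disability
#' weights are mutually independent; the model states no correlation
#' structure.
#'
#' @param specs A list of [outcome_spec()] objects.
#' @param config A [psa_config()].
#' @return An object of class `draw_matrix`: a list with matrices
#'   `risk_control`, `risk_intervention`, `ard`, `dw`, `dalys` (each
#'   `n_sims x n_outcomes`, columns named by outcome) and the numeric
#'   vector `total` (row sums of `dalys`), plus the generating `config`.
#' @export
sample_draws <- function(specs, config = psa_config()) {
  stopifnot(inherits(config, "psa_config"))
  if (inherits(specs, "outcome_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop("'specs' must be nonempty", call. = FALSE)
  for (s in specs) stopifnot(inherits(s, "outcome_spec"))
  n <- config$n_sims
  labels <- vapply(specs, `[[`, character(1), "name")
  mk <- function() matrix(NA_real_, n, length(specs), dimnames = list(NULL, labels))
  out <- list(risk_control = mk(), risk_intervention = mk(),
              ard = mk(), dw = mk(), dalys = mk())
  set.seed(config$seed)
  for (j in seq_along(specs)) {
    s <- specs[[j]]
    rc <- draw_risk(n, s$risk_control["mean"], s$risk_control["sd"], config$risk_family)
    ri <- draw_risk(n, s$risk_intervention["mean"], s$risk_intervention["sd"], config$risk_family)
    dw <- draw_dw(n, s$dw["mean"], s$dw["sd"])
    out$risk_control[, j] <- rc
    out$risk_intervention[, j] <- ri
    out$ard[, j] <- ri - rc
    out$dw[, j] <- dw
    out$dalys[, j] <- dalys_averted(ri - rc, dw)
  }
  out$total <- rowSums(out$dalys)
  out$config <- config
  class(out) <- "draw_matrix"
  out
}

#' @export
print.draw_matrix <- function(x, ...) {
  cat(sprintf("<draw_matrix> %d simulations x %d outcomes (%s risks, seed %d)\n",
              nrow(x$dalys), ncol(x$dalys), x$config$risk_family, x$config$seed))
  pi <- predicted_interval(x$total, x$config)
  cat(sprintf("  total DALYs averted: mean %.4f, PI [%.4f, %.4f]\n",
              mean(x$total), pi[1], pi[2]))
  invisible(x)
}

#' Predicted interval of a simulated quantity
#'
#' Empirical percentiles of a per-simulation column at the configured pair
#' (default 5th and 95th), with linear interpolation between order
#' statistics. Note that the 5th-95th percentile range is, by the usual
#' coverage convention, a 90% interval; the percentile pair is exposed in
#' [psa_config()] for users who prefer 2.5/97.5.
#'
#' @param values Numeric vector of per-simulation values.
#' @param config A [psa_config()] (only `pi_percentiles` is used).
#' @return Numeric length-2 vector `c(low, high)`.
#' @export
predicted_interval <- function(values, config = psa_config()) {
  p <- config$pi_percentiles / 100
  q <- stats::quantile(values, probs = p, names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}
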