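#' Configuration for a synthetic two-arm trial
#'
#' Describes an individually randomized two-arm trial with binary endline
#' outcomes: each participant is retained independently with probability
#' `1 - dropout_rate` (missing completely at random), and each outcome is
#' an independent Bernoulli draw at the arm's true risk. This is the
#' statistical structure the downstream risk summaries assume; no
#' longitudinal or covariate structure is modelled.
#'
#' @param n_per_arm Participants randomized to each arm (>= 1).
#' @param true_risks Named list: one element per outcome, each a numeric
#'   `c(control = p, intervention = p)` pair of true endline risks in
#'   \[0, 1\].
#' @param dropout_rate Probability a participant is lost before endline.
#' @param seed Integer seed.
#' @return An object of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_per_arm, true_risks, dropout_rate = 0, seed = 1L) {
  n_per_arm <- as.integer(n_per_arm)
  if (is.na(n_per_arm) || n_per_arm < 1L)
    stop("'n_per_arm' must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("'dropout_rate' must be in [0, 1]", call. = FALSE)
  if (!is.list(true_risks) || is.null(names(true_risks)) ||
      any(!nzchar(names(true_risks))))
    stop("'true_risks' must be a named list of c(control, intervention) pairs",
         call. = FALSE)
  for (nm in names(true_risks)) {
    p <- true_risks[[nm]]
    if (!is.numeric(p) || length(p) != 2L || any(p < 0) || any(p > 1))
      stop(sprintf("true risks for '%s' must be two probabilities in [0, 1]", nm),
           call. = FALSE)
    if (is.null(names(p))) names(true_risks[[nm]]) <- c("control", "intervention")
  }
  structure(list(n_per_arm = n_per_arm, true_risks = true_risks,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Simulate individual-level trial records
#'
#' Draws, per arm: a retained flag for every randomized participant
#' (independent Bernoulli at `1 - dropout_rate`), then each outcome's
#' binary endline value at the arm's true risk, independently across
#' participants and outcomes. Outcome values are generated for everyone
#' (dropout is independent of outcomes by construction); estimation later
#' restricts to retained participants.
#'
#' @param config A [trial_sim_config()].
#' @return Data frame with `participant_id`, `arm`, `retained`, and one
#'   0/1 column per outcome.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_sim_config"))
  set.seed(config$seed)
  n <- config$n_per_arm
  arms <- c("control", "intervention")
  rows <- lapply(arms, function(arm) {
    df <- data.frame(
      participant_id = paste0(substr(arm, 1, 1), seq_len(n)),
      arm = arm,
      retained = stats::runif(n) < (1 - config$dropout_rate),
      stringsAsFactors = FALSE)
    for (nm in names(config$true_risks)) {
      p <- config$true_risks[[nm]][[arm]]
      df[[nm]] <- as.integer(stats::runif(n) < p)
    }
    df
  })
  do.call(rbind, rows)
}

#' Estimate arm-level risk summaries from trial records
#'
#' Restricts to retained participants and reports, per arm, the endline
#' risk on the percent scale with its binomial standard error in
#' percentage points: `risk_mean = 100 * k/n` and
#' `risk_sd = 100 * sqrt(p_hat * (1 - p_hat) / n)`.
#'
#' @param records Data frame from [simulate_trial()].
#' @param outcome Name of the outcome column.
#' @return Data frame with one row per arm: `outcome`, `arm`, `risk_mean`
#'   (percent), `risk_sd` (percentage points), `n_used`.
#' @export
estimate_risks <- function(records, outcome) {
  if (!outcome %in% names(records))
    stop(sprintf("outcome '%s' not found in records", outcome), call. = FALSE)
  kept <- records[records$retained, , drop = FALSE]
  arms <- c("control", "intervention")
  out <- lapply(arms, function(arm) {
    x <- kept[[outcome]][kept$arm == arm]
    n <- length(x)
    if (n == 0L)
      stop(sprintf("no retained participants in the %s arm", arm), call. = FALSE)
    p_hat <- mean(x)
    data.frame(outcome = outcome, arm = arm,
               risk_mean = 100 * p_hat,
               risk_sd = 100 * sqrt(p_hat * (1 - p_hat) / n),
               n_used = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standard deviation from a mean and an upper confidence limit
#'
#' Recovers the SD a normal approximation implies for a reported mean and
#' upper 95% confidence limit: `(upper_limit - mean) / 1.96`. This is the
#' rule used to turn published risk confidence intervals into the SDs the
#' probabilistic model samples from, and it is the exact inverse of
#' `upper = mean + 1.96 * sd`.
#'
#' @param mean,upper_limit Percent-scale mean and upper limit
#'   (`upper_limit >= mean`).
#' @return SD in percentage points.
#' @examples
#' sd_from_ci(50, 59.8)  # 5
#' @export
sd_from_ci <- function(mean, upper_limit) {
  if (upper_limit < mean)
    stop("'upper_limit' must be >= 'mean'", call. = FALSE)
  (upper_limit - mean) / 1.96
}
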