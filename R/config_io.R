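LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L)

log_msg <- function(level = "info", ...) {
  threshold <- getOption("dalyeval.log_level", "info")
  if (LOG_LEVELS[[level]] >= LOG_LEVELS[[threshold]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

check_known_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L)
    stop(sprintf("unknown key%s in %s: %s",
                 if (length(unknown) > 1) "s" else "", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  invisible(NULL)
}

mean_sd <- function(x, key) {
  if (is.null(x) || is.null(x$mean) || is.null(x$sd))
    stop(sprintf("'%s' must have 'mean' and 'sd'", key), call. = FALSE)
  c(x$mean, x$sd)
}

#' Load and validate an evaluation config
#'
#' Reads a YAML config with named sections (`outcomes`, `psa`, `costing`,
#' `cea`, `bia`, plus `output_dir` and `log_level`) and builds the typed
#' configuration objects each analysis stage consumes. Unknown keys are
#' rejected by name. Sections are validated lazily: only the sections
#' named in `sections` must be present and valid, so a config without a
#' `bia` section still serves the cost and cost-effectiveness analyses;
#' sections that are present are always validated. Validation failures
#' are collected and reported together, one line per failing key.
#'
#' @param path Path to the YAML config.
#' @param sections Character vector of required sections (default: all
#'   that are present).
#' @return An object of class `evaluation_config`: a list with
#'   `outcomes` (list of [outcome_spec()]), `psa` ([psa_config()]),
#'   `costing` ([costing_config()]), `cea` (threshold settings), `bia`
#'   ([bia_config()]), `ledger_path`, `output_dir`, `log_level`, and
#'   `path`.
#' @export
load_config <- function(path, sections = NULL) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_known_keys(raw, c("outcomes", "psa", "costing", "cea", "bia",
                          "output_dir", "log_level"), "config")
  if (is.null(sections))
    sections <- intersect(c("outcomes", "psa", "costing", "cea", "bia"), names(raw))
  missing <- setdiff(sections, names(raw))
  if (length(missing) > 0L)
    stop(sprintf("required section%s missing from config: %s",
                 if (length(missing) > 1) "s" else "",
                 paste(missing, collapse = ", ")), call. = FALSE)

  errors <- character(0)
  note <- function(e) errors <<- c(errors, conditionMessage(e))
  cfg <- list(path = normalizePath(path),
              output_dir = raw$output_dir %||% ".",
              log_level = raw$log_level %||% "info")
  if (!cfg$log_level %in% names(LOG_LEVELS))
    errors <- c(errors, sprintf("log_level must be one of %s",
                                paste(names(LOG_LEVELS), collapse = ", ")))

  if (!is.null(raw$outcomes)) {
    cfg$outcomes <- list()
    for (i in seq_along(raw$outcomes)) {
      o <- raw$outcomes[[i]]
      tryCatch({
        check_known_keys(o, c("name", "risk_control", "risk_intervention", "dw"),
                         sprintf("outcomes[%d]", i))
        cfg$outcomes[[length(cfg$outcomes) + 1L]] <-
          outcome_spec(o$name,
                       mean_sd(o$risk_control, "risk_control"),
                       mean_sd(o$risk_intervention, "risk_intervention"),
                       mean_sd(o$dw, "dw"))
      }, error = function(e) note(simpleError(
        sprintf("outcomes[%d] (%s): %s", i, o$name %||% "?", conditionMessage(e)))))
    }
  }

  if (!is.null(raw$psa)) {
    tryCatch({
      check_known_keys(raw$psa, c("n_sims", "seed", "risk_family", "pi_percentiles"),
                       "psa")
      cfg$psa <- psa_config(
        n_sims = raw$psa$n_sims %||% 10000L,
        seed = raw$psa$seed %||% 1L,
        risk_family = raw$psa$risk_family %||% "normal",
        pi_percentiles = unlist(raw$psa$pi_percentiles %||% c(5, 95)))
    }, error = note)
  }

  if (!is.null(raw$costing)) {
    tryCatch({
      cs <- raw$costing
      check_known_keys(cs, c("ledger", "n_usual_care_denominator",
                             "n_intervention_denominator",
                             "per_person_usual_care", "per_person_intervention",
                             "time_with_outreach", "time_without_outreach",
                             "contacts_per_person", "hourly_wage",
                             "outreach_contact_rate_intervention",
                             "outreach_contact_rate_control"), "costing")
      args <- cs[setdiff(names(cs), "ledger")]
      cfg$costing <- do.call(costing_config, args)
      if (!is.null(cs$ledger)) {
        cfg$ledger_path <- if (file.exists(cs$ledger)) cs$ledger
                           else file.path(dirname(path), cs$ledger)
      }
    }, error = note)
  }

  if (!is.null(raw$cea)) {
    tryCatch({
      check_known_keys(raw$cea, c("threshold_range", "lambda_grid_max",
                                  "lambda_grid_step"), "cea")
      tr <- unlist(raw$cea$threshold_range %||% c(835, 1671))
      if (length(tr) != 2L || tr[1] > tr[2])
        stop("cea threshold_range must be an ordered pair", call. = FALSE)
      cfg$cea <- list(threshold_range = as.numeric(tr),
                      lambda_grid_max = raw$cea$lambda_grid_max %||% 50000,
                      lambda_grid_step = raw$cea$lambda_grid_step %||% 250)
    }, error = note)
  }

  if (!is.null(raw$bia)) {
    tryCatch({
      check_known_keys(raw$bia, names(formals(bia_config)), "bia")
      cfg$bia <- do.call(bia_config, raw$bia)
    }, error = note)
  }

  if (length(errors) > 0L)
    stop(sprintf("invalid config '%s':\n  - %s", path,
                 paste(errors, collapse = "\n  - ")), call. = FALSE)
  structure(cfg, class = "evaluation_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cost ledger CSV
#'
#' The ledger is a flat expenditure file with the exact header
#' `funder,activity,input_type,amount_usd,arm_scope`. Each line is one
#' expenditure: who paid (`expertise_france` or `global_fund`), the
#' activity (`diagnosis_treatment`, `iec` — information, education, and
#' communication — or `program_management`), the input type
#' (`consumables` or `personnel`), the 2019 US $ amount, and whether the
#' money benefited `both_arms` or the `intervention_only`.
#'
#' @param path Path to the CSV.
#' @return A data frame of validated ledger entries (possibly zero rows).
#' @export
load_cost_ledger <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cost ledger not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        colClasses = "character")
  expected <- c("funder", "activity", "input_type", "amount_usd", "arm_scope")
  if (!identical(names(df), expected))
    stop(sprintf("ledger header must be exactly '%s'",
                 paste(expected, collapse = ",")), call. = FALSE)
  amount <- suppressWarnings(as.numeric(df$amount_usd))
  if (nrow(df) > 0L && anyNA(amount))
    stop(sprintf("unparseable amount_usd: %s",
                 paste(unique(df$amount_usd[is.na(amount)]), collapse = ", ")),
         call. = FALSE)
  df$amount_usd <- amount
  check_enum <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad) > 0L)
      stop(sprintf("unknown %s value%s: %s", col,
                   if (length(bad) > 1) "s" else "",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) > 0L) {
    check_enum("funder", FUNDER_LEVELS)
    check_enum("activity", ACTIVITY_LEVELS)
    check_enum("input_type", INPUT_TYPE_LEVELS)
    check_enum("arm_scope", ARM_SCOPE_LEVELS)
    if (any(df$amount_usd < 0))
      stop("amount_usd must be non-negative", call. = FALSE)
  }
  df
}

#' Build a result table
#'
#' A result table is a data frame of labelled numeric cells plus the run
#' metadata (seed, number of simulations, distribution family,
#' perspective, ...) sufficient to re-run the producing command
#' bit-identically.
#'
#' @param data A data frame.
#' @param metadata Named list of run metadata.
#' @return An object of class `result_table`.
#' @export
result_table <- function(data, metadata = list()) {
  stopifnot(is.data.frame(data), is.list(metadata))
  structure(list(data = data, metadata = metadata), class = "result_table")
}

#' @export
print.result_table <- function(x, ...) {
  cat("<result_table>\n")
  print(x$data)
  if (length(x$metadata) > 0L)
    cat("metadata:", paste(names(x$metadata),
                           vapply(x$metadata, function(v) paste(format(v), collapse = " "),
                                  character(1)),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

metadata_path <- function(path) paste0(tools::file_path_sans_ext(path), ".meta.json")

#' Write a result table to CSV with a JSON metadata sidecar
#'
#' Numeric cells are serialized at full double precision (17 significant
#' digits) so that [read_results()] round-trips losslessly; metadata goes
#' to `<stem>.meta.json`.
#'
#' @param table A [result_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(inherits(table, "result_table"))
  dir <- dirname(path)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  df <- table$data
  for (j in seq_along(df))
    if (is.numeric(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(table$metadata, metadata_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_msg("info", "wrote ", path, " (+ ", basename(metadata_path(path)), ")")
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path The CSV path.
#' @return A [result_table()] with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(x) || all(is.na(x) == (df[[j]] %in% c("NA", ""))))
      df[[j]] <- x
  }
  meta <- if (file.exists(metadata_path(path)))
    jsonlite::read_json(metadata_path(path), simplifyVector = TRUE)
  else list()
  result_table(df, as.list(meta))
}

#' Path to a bundled example file
#'
#' The package ships a worked-example fixture set under `extdata`: an
#' evaluation config (`evaluation.yaml`) whose five outcomes carry the
#' published endline risks and disability weights, and a cost ledger
#' (`cost_ledger.csv`) with the trial's payer expenditure lines.
#'
#' @param file File name; with no argument, lists the available files.
#' @return A path, or a character vector of file names.
#' @examples
#' dalyeval_example()
#' cfg <- load_config(dalyeval_example("evaluation.yaml"))
#' @export
dalyeval_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "dalyeval")))
  path <- system.file("extdata", file, package = "dalyeval")
  if (path == "")
    stop(sprintf("no bundled file '%s'", file), call. = FALSE)
  path
}
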