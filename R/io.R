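# CSV / JSON interchange.

trial_col_types <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    experiment_mode = readr::col_character(),
    block = readr::col_integer(),
    phase = readr::col_character(),
    trial = readr::col_integer(),
    action_or_cue = readr::col_character(),
    adaptation_order = readr::col_character(),
    outcome_predicted = readr::col_logical(),
    soa_ms = readr::col_double(),
    is_catch = readr::col_logical(),
    response = readr::col_character()
  )
}

#' Read / write tidy trial tables
#'
#' One trial per row with the fixed header `subject_id, experiment_mode,
#' block, phase, trial, action_or_cue, adaptation_order, outcome_predicted,
#' soa_ms, is_catch, response`; missing values (e.g. `outcome_predicted` on
#' learning trials) are empty fields.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `read_trials_csv()` returns the trial tibble;
#'   `write_trials_csv()` returns `path` invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  stopifnot(identical(names(trials), names(empty_trials())))
  write_atomically(function(p) readr::write_csv(trials, p, na = ""), path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  out <- readr::read_csv(path, col_types = trial_col_types(), na = "")
  missing <- setdiff(names(empty_trials()), names(out))
  if (length(missing)) {
    abort(paste0("Trial CSV is missing column(s): ", paste(missing, collapse = ", ")),
          class = "avrecal_data_error")
  }
  out$response[is.na(out$response)] <- "none"
  out
}

#' Read / write psychometric-fit tables
#'
#' Columns: `subject_id, condition, adaptation_order, outcome_predicted,
#' alpha_ms, sigma_ms, scale, sse_weighted, r_squared, converged,
#' n_restarts_used, incomplete`.
#'
#' @param fits Fits tibble from [fit_all()].
#' @param path File path.
#' @return `read_fits_csv()` returns the fits tibble.
#' @export
write_fits_csv <- function(fits, path) {
  write_atomically(function(p) readr::write_csv(fits, p, na = ""), path)
}

#' @rdname write_fits_csv
#' @export
read_fits_csv <- function(path) {
  readr::read_csv(path, na = "", col_types = readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_character(),
    adaptation_order = readr::col_character(),
    outcome_predicted = readr::col_logical(),
    .default = readr::col_guess()
  ))
}

#' Read a run configuration from JSON
#'
#' All fields are optional and fall back to the package defaults: top-level
#' `experiment_mode`, `n_subjects`, `seed`, `out_dir`, plus nested objects
#' `design` (fields of [design_config()]), `population` (fields of
#' [population_spec()]) and `exclusion` (fields of [exclusion_rule()]).
#'
#' @param path Path to a JSON file.
#' @param ... Overrides forwarded to [run_config()], taking precedence over
#'   the file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("experiment_mode", "n_subjects", "seed", "out_dir",
             "design", "population", "exclusion")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "avrecal_config_error")
  }
  args <- raw
  args$design <- if (!is.null(raw$design)) do.call(design_config, raw$design)
  args$population_overrides <- raw$population
  args$population <- NULL
  args$exclusion <- if (!is.null(raw$exclusion)) do.call(exclusion_rule, raw$exclusion)
  args[vapply(args, is.null, logical(1))] <- NULL
  overrides <- list(...)
  do.call(run_config, modifyList(args, overrides))
}

#' Validate the structure of a statistical report
#'
#' Lightweight structural validation of the report written by
#' [run_pipeline()] against the schema shipped in
#' `system.file("schema", "stat_report.schema.json", package = "avrecal")`:
#' checks required keys and basic types.
#'
#' @param report A stat-report list (or a path to its JSON file).
#' @return `TRUE` invisibly; aborts with the missing/malformed keys
#'   otherwise.
#' @export
validate_stat_report <- function(report) {
  if (is.character(report) && length(report) == 1L) {
    report <- jsonlite::read_json(report, simplifyVector = TRUE)
  }
  required <- c("experiment_mode", "seed", "n_subjects_simulated",
                "n_subjects_analyzed", "exclusions", "condition_means",
                "inference_performed", "config")
  missing <- setdiff(required, names(report))
  if (length(missing)) {
    abort(paste0("Report is missing key(s): ", paste(missing, collapse = ", ")),
          class = "avrecal_schema_error")
  }
  if (isTRUE(report$inference_performed)) {
    needed <- c("anova", "t_tests", "bias_tests", "achieved_power")
    missing <- setdiff(needed, names(report))
    if (length(missing)) {
      abort(paste0("Report with inference is missing key(s): ",
                   paste(missing, collapse = ", ")),
            class = "avrecal_schema_error")
    }
    if (!all(c("effect", "F", "df1", "df2", "p", "partial_eta_sq") %in%
             names(report$anova))) {
      abort("Report `anova` table is malformed.", class = "avrecal_schema_error")
    }
  }
  invisible(TRUE)
}
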