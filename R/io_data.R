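#' @title Trial-level behavioral tables
#' @description
#' The package's central data container is a tidy trial table: one row per
#' trial of the 2x2 (valence x feedback) probabilistic instrumental learning
#' task. Required columns:
#'
#' * `experiment_id`, `participant_id` — labels.
#' * `session` — positive integer.
#' * `trial_index` — integer >= 1, strictly increasing within
#'   participant x session.
#' * `context_valence` — `"reward"` or `"punishment"`.
#' * `context_feedback` — `"partial"` or `"complete"`.
#' * `correct` — 1 if the option with the highest mean payoff was chosen,
#'   0 otherwise; `NA` for omitted (non-response) trials.
#' * `rt` — response time in seconds, in `(0, response_window]`; `NA` for
#'   non-response trials.
#' * `outcome_chosen` — received payoff in points (`-1`, `0`, `+1` for the
#'   unit-stakes task); `NA` for non-response trials.
#' * `outcome_unchosen` — forgone payoff; non-missing exactly on responded
#'   complete-feedback trials.
#' * `response_window` — seconds (3.0 or 1.5 depending on the experiment).
#'
#' Non-response trials (no button press within the window) carry `NA` in
#' `correct`, `rt` and the outcome columns, and are excluded from all
#' model-fitting operations.
#' @name trial_table
NULL

trial_table_columns <- c(
  "experiment_id", "participant_id", "session", "trial_index",
  "context_valence", "context_feedback", "correct", "rt",
  "outcome_chosen", "outcome_unchosen", "response_window"
)

new_trial_table <- function(df, design = NULL) {
  out <- tibble::as_tibble(df)
  class(out) <- c("trial_table", class(out))
  attr(out, "design") <- design
  out
}

#' Validate a trial table
#'
#' Checks the full schema contract and every invariant; violations raise a
#' classed error (`rlddm_schema_error` for missing/mistyped columns,
#' `rlddm_validation_error` otherwise) whose message names the offending
#' column and row indices. Validation never coerces silently.
#'
#' @param data A data frame in the [trial_table] schema.
#' @param design Optional [task_design] used to cross-check the response
#'   window.
#' @return The validated data, classed as `trial_table`, invisibly unchanged.
#' @export
validate_trial_table <- function(data, design = NULL) {
  missing_cols <- setdiff(trial_table_columns, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("trial table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rlddm_schema_error")
  }
  bad_valence <- which(!data$context_valence %in% c("reward", "punishment"))
  if (length(bad_valence) > 0) {
    abort(paste0("context_valence must be 'reward' or 'punishment'; rows: ",
                 row_list(bad_valence)), class = "rlddm_validation_error")
  }
  bad_feedback <- which(!data$context_feedback %in% c("partial", "complete"))
  if (length(bad_feedback) > 0) {
    abort(paste0("context_feedback must be 'partial' or 'complete'; rows: ",
                 row_list(bad_feedback)), class = "rlddm_validation_error")
  }
  responded <- !is.na(data$rt)
  bad_correct <- which(responded & !data$correct %in% c(0, 1))
  if (length(bad_correct) > 0) {
    abort(paste0("correct must be 0/1 on responded trials; rows: ",
                 row_list(bad_correct)), class = "rlddm_validation_error")
  }
  win <- data$response_window
  if (!is.null(design)) {
    if (any(abs(win - design$response_window) > 1e-9)) {
      abort("response_window does not match the supplied design",
            class = "rlddm_validation_error")
    }
  }
  bad_rt <- which(responded & !(data$rt > 0 & data$rt <= win))
  if (length(bad_rt) > 0) {
    abort(paste0("rt must lie in (0, response_window] on responded trials; ",
                 "rows: ", row_list(bad_rt)), class = "rlddm_validation_error")
  }
  # forgone outcome present iff complete feedback (on responded trials)
  complete <- data$context_feedback == "complete"
  bad_unch <- which(responded &
                      (complete != !is.na(data$outcome_unchosen)))
  if (length(bad_unch) > 0) {
    abort(paste0("outcome_unchosen must be present exactly on responded ",
                 "complete-feedback trials; rows: ", row_list(bad_unch)),
          class = "rlddm_validation_error")
  }
  # trial ordering within participant x session
  key <- paste(data$experiment_id, data$participant_id, data$session)
  for (k in unique(key)) {
    idx <- which(key == k)
    ti <- data$trial_index[idx]
    if (anyNA(ti) || any(ti < 1) || any(diff(ti) <= 0)) {
      abort(paste0("trial_index must be >= 1 and strictly increasing within ",
                   "participant x session; violated for ", k),
            class = "rlddm_validation_error")
    }
    ctx <- unique(paste(data$context_valence[idx], data$context_feedback[idx]))
    if (length(ctx) != 4) {
      abort(paste0("each participant x session must contain all four ",
                   "contexts; missing for ", k),
            class = "rlddm_validation_error")
    }
  }
  new_trial_table(data, design = design %||% attr(data, "design"))
}

row_list <- function(idx, max_show = 10) {
  shown <- paste(head(idx, max_show), collapse = ", ")
  if (length(idx) > max_show) shown <- paste0(shown, ", ... (", length(idx), " total)")
  shown
}

#' Read a trial table from CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a mandatory header and `.` as
#' decimal separator; response times are stored in seconds. Ground-truth
#' columns written by the simulator (prefix `true_`) are carried along
#' untouched.
#'
#' @param path Path to a CSV file in the [trial_table] schema.
#' @param design Optional [task_design] for cross-validation.
#' @return A validated `trial_table`; row order is preserved.
#' @seealso [write_trial_table()]
#' @export
load_trial_table <- function(path, design = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "rlddm_io_error")
  }
  spec <- readr::cols(
    experiment_id = readr::col_character(),
    participant_id = readr::col_character(),
    session = readr::col_integer(),
    trial_index = readr::col_integer(),
    context_valence = readr::col_character(),
    context_feedback = readr::col_character(),
    correct = readr::col_double(),
    rt = readr::col_double(),
    outcome_chosen = readr::col_double(),
    outcome_unchosen = readr::col_double(),
    response_window = readr::col_double(),
    .default = readr::col_double()
  )
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(trial_table_columns, header)
  if (length(missing_cols) > 0) {
    abort(paste0("CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rlddm_schema_error")
  }
  df <- readr::read_csv(path, col_types = spec, show_col_types = FALSE)
  validate_trial_table(df, design = design)
}

#' Write a trial table to CSV
#'
#' Inverse of [load_trial_table()]: a write-then-read round trip reproduces
#' the table exactly.
#'
#' @param data A `trial_table` (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path) {
  data <- validate_trial_table(data)
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Read a key-value configuration file (JSON or YAML)
#'
#' Holds sampler settings, seeds and design presets for the command-line
#' interface; keys mirror the arguments of the fitting functions.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "rlddm_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the 'yaml' package is required for YAML configs",
            class = "rlddm_io_error")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
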