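# CSV / JSON serialization. All tables round-trip through plain text; headers
# carry scalar metadata as "# key=value" comment lines.

COHORT_COLS <- c(
  "subject_id", "age", "entered_age", "sex", "bmi", "sbp", "dbp", "map",
  "heart_rate", "true_pwv", "ict", "distance"
)
FIDUCIAL_COLS <- c("subject_id", "beat_index", "t_r_hat", "t_valve_hat", "t_foot_hat", "valid")
RECORD_COLS <- c(
  "subject_id", "pat", "ict_hat", "cpat", "distance", "measured_pwv",
  "est_rep1", "est_rep2", "est_rep3", "estimated_pwv"
)

check_required_cols <- function(df, required, path, warn_extra = TRUE) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    pwv_abort(
      paste0(
        "file ", path, " is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      "format_error"
    )
  }
  extra <- setdiff(names(df), required)
  if (warn_extra && length(extra)) {
    rlang::warn(paste0(
      "file ", path, " has unknown column(s), preserved: ",
      paste(extra, collapse = ", ")
    ))
  }
  invisible(df)
}

read_table_quiet <- function(path, comment = "") {
  if (!file.exists(path)) {
    pwv_abort(paste0("file not found: ", path), "format_error")
  }
  readr::read_csv(path, comment = comment, show_col_types = FALSE, progress = FALSE)
}

#' Write / read a cohort table
#'
#' CSV with exactly the subject columns of [draw_cohort()] first; any extra
#' columns are preserved (with a warning on read).
#'
#' @param cohort A `pwv_cohort` tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()` its
#'   path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_required_cols(cohort, COHORT_COLS, path = "<cohort>", warn_extra = FALSE)
  readr::write_csv(cohort[, union(COHORT_COLS, names(cohort))], path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read_table_quiet(path)
  check_required_cols(df, COHORT_COLS, path)
  df$entered_age <- as.integer(df$entered_age)
  validate_cohort(df)
  structure(df, class = c("pwv_cohort", class(df)))
}

#' Write / read a waveform bundle
#'
#' The recording is stored as CSV with header comment lines
#' `# sampling_rate_hz=<float>`, `# subject_id=<id>` and
#' `# duration_s=<float>`, followed by columns `t, ecg, doppler_env, cuff`.
#' Truth annotations go to a sibling CSV (`beat_index, t_r, t_valve, t_foot`),
#' by default `<path>_truth.csv`.
#'
#' @param bundle A `waveform_bundle`.
#' @param path Recording CSV path.
#' @param truth_path Annotation CSV path, or `NULL` for the default sibling;
#'   `NA` to skip truth on write / tolerate a missing file on read.
#' @return `read_waveform_bundle()` returns a `waveform_bundle`.
#' @export
write_waveform_bundle <- function(bundle, path, truth_path = NULL) {
  stopifnot(inherits(bundle, "waveform_bundle"))
  header <- c(
    sprintf("# sampling_rate_hz=%.6f", bundle$sampling_rate),
    sprintf("# subject_id=%s", bundle$subject_id),
    sprintf("# duration_s=%.6f", bundle$duration)
  )
  writeLines(header, path)
  readr::write_csv(bundle$channels, path, append = TRUE, col_names = TRUE)
  if (!isTRUE(is.na(truth_path))) {
    truth_path <- truth_path %||% default_truth_path(path)
    readr::write_csv(bundle$truth, truth_path)
  }
  invisible(path)
}

default_truth_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0("_truth.csv")
}

parse_header_value <- function(lines, key) {
  hit <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)
  if (!length(hit)) {
    return(NULL)
  }
  sub(paste0("^#\\s*", key, "="), "", hit[1])
}

#' @rdname write_waveform_bundle
#' @export
read_waveform_bundle <- function(path, truth_path = NULL) {
  if (!file.exists(path)) {
    pwv_abort(paste0("file not found: ", path), "format_error")
  }
  head_lines <- readLines(path, n = 10)
  head_lines <- head_lines[startsWith(head_lines, "#")]
  fs <- parse_header_value(head_lines, "sampling_rate_hz")
  if (is.null(fs)) {
    pwv_abort(paste0("file ", path, " lacks a '# sampling_rate_hz=' header"), "format_error")
  }
  fs <- as.numeric(fs)
  subject_id <- parse_header_value(head_lines, "subject_id") %||% "subject"
  channels <- read_table_quiet(path, comment = "#")
  check_required_cols(channels, c("t", "ecg", "doppler_env", "cuff"), path)
  duration <- parse_header_value(head_lines, "duration_s")
  duration <- if (is.null(duration)) nrow(channels) / fs else as.numeric(duration)
  truth_path <- truth_path %||% default_truth_path(path)
  truth <- NULL
  if (!isTRUE(is.na(truth_path)) && file.exists(truth_path)) {
    truth <- read_table_quiet(truth_path)
    check_required_cols(truth, c("beat_index", "t_r", "t_valve", "t_foot"), truth_path)
  }
  structure(
    list(
      subject_id = subject_id, sampling_rate = fs, duration = duration,
      channels = channels, truth = truth
    ),
    class = "waveform_bundle"
  )
}

#' Write / read a fiducial table
#'
#' CSV with columns `subject_id, beat_index, t_r_hat, t_valve_hat,
#' t_foot_hat, valid`.
#'
#' @param fiducials A `pwv_fiducials` tibble (see [detect_fiducials()]).
#' @param path File path.
#' @export
write_fiducials <- function(fiducials, path) {
  df <- tibble::as_tibble(fiducials)
  if (!"subject_id" %in% names(df)) {
    df$subject_id <- attr(fiducials, "subject_id") %||% "subject"
  }
  readr::write_csv(df[, union(FIDUCIAL_COLS, names(df))], path)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  df <- read_table_quiet(path)
  check_required_cols(df, FIDUCIAL_COLS, path)
  structure(df, class = c("pwv_fiducials", class(df)))
}

#' Write / read per-subject PWV records
#'
#' CSV with the per-subject measured and triplicate estimated PWV values:
#' `subject_id, pat, ict_hat, cpat, distance, measured_pwv, est_rep1..3,
#' estimated_pwv`, plus any additional columns present.
#'
#' @param records A `pwv_records` tibble (see [compute_pwv()]).
#' @param path File path.
#' @export
write_pwv_records <- function(records, path) {
  check_required_cols(records, RECORD_COLS, path = "<records>", warn_extra = FALSE)
  readr::write_csv(records[, union(RECORD_COLS, names(records))], path)
  invisible(path)
}

#' @rdname write_pwv_records
#' @export
read_pwv_records <- function(path) {
  df <- read_table_quiet(path)
  check_required_cols(df, RECORD_COLS, path)
  structure(df, class = c("pwv_records", class(df)))
}
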