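# Score records: one row per trial x latency interval.
#
# Statuses: "auto" (algorithmic), "adjusted" (manually overridden), "zero"
# (non-response, amplitude 0, coordinates empty), "missing_artifact"
# (excluded from statistics, not treated as 0).

score_cols <- function() {
  c("event_index", "interval", "trough_time_s", "trough_value_uS",
    "peak_time_s", "peak_value_uS", "amplitude_uS", "status", "rater")
}

new_score_record <- function(event_index, interval, trough_time_s = NA_real_,
                             trough_value_uS = NA_real_, peak_time_s = NA_real_,
                             peak_value_uS = NA_real_, amplitude_uS = 0,
                             status = "zero", rater = "auto") {
  tibble(event_index = as.integer(event_index),
         interval = factor(interval, levels = interval_levels()),
         trough_time_s = trough_time_s, trough_value_uS = trough_value_uS,
         peak_time_s = peak_time_s, peak_value_uS = peak_value_uS,
         amplitude_uS = amplitude_uS, status = status, rater = rater)
}

#' Validate a table of score records
#'
#' Checks the per-row invariants: responses (`auto`/`adjusted`) must have
#' trough before peak and a positive amplitude equal to the value
#' difference; `zero` rows carry amplitude 0 and empty coordinates;
#' `missing_artifact` rows carry NA amplitude.  Keys
#' (event_index, interval, rater) must be unique.
#'
#' @param records Data frame of score records (see [write_scores()] for the
#'   column schema).
#' @return The validated records as a tibble, invisibly classed
#'   `scr_scores`, sorted by (rater, event_index, interval).
#' @export
validate_scores <- function(records) {
  records <- as_tibble(records)
  missing_cols <- setdiff(score_cols(), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing score columns: ", paste(missing_cols, collapse = ", ")),
          class = "scr_validation_error")
  }
  if (nrow(records) == 0) {
    abort("Score table is empty.", class = "scr_validation_error")
  }
  if (!all(as.character(records$interval) %in% interval_levels())) {
    bad <- setdiff(unique(as.character(records$interval)), interval_levels())
    abort(sprintf("Unknown interval token(s): %s", paste(bad, collapse = ", ")),
          class = "scr_parse_error")
  }
  records$interval <- factor(as.character(records$interval),
                             levels = interval_levels())
  if (!all(records$status %in% score_statuses())) {
    abort(sprintf("Unknown status value(s): %s",
                  paste(setdiff(unique(records$status), score_statuses()),
                        collapse = ", ")),
          class = "scr_parse_error")
  }
  key <- paste(records$event_index, records$interval, records$rater)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate score record(s) for (event, interval, rater): %s",
                  paste(unique(key[duplicated(key)]), collapse = "; ")),
          class = "scr_validation_error")
  }
  resp <- records$status %in% c("auto", "adjusted")
  bad_resp <- resp & !(is.finite(records$trough_time_s) &
                         is.finite(records$peak_time_s) &
                         records$trough_time_s < records$peak_time_s &
                         records$amplitude_uS > 0 &
                         abs(records$amplitude_uS -
                               (records$peak_value_uS - records$trough_value_uS)) < 5e-6)
  if (any(bad_resp)) {
    abort(sprintf("Invalid response record(s) at row(s) %s: need trough before peak and amplitude = peak - trough > 0.",
                  paste(which(bad_resp), collapse = ", ")),
          class = "scr_validation_error")
  }
  zero <- records$status == "zero"
  bad_zero <- zero & !(records$amplitude_uS == 0 &
                         is.na(records$trough_time_s) & is.na(records$peak_time_s) &
                         is.na(records$trough_value_uS) & is.na(records$peak_value_uS))
  if (any(bad_zero)) {
    abort(sprintf("Invalid zero record(s) at row(s) %s: amplitude must be 0 with empty coordinates.",
                  paste(which(bad_zero), collapse = ", ")),
          class = "scr_validation_error")
  }
  miss <- records$status == "missing_artifact"
  records$amplitude_uS[miss] <- NA_real_
  records <- dplyr::arrange(records, .data$rater, .data$event_index,
                            .data$interval)
  class(records) <- c("scr_scores", class(records))
  invisible(records)
}

#' Write score records to an annotation CSV
#'
#' Stable column order, times with millisecond precision, empty cells for
#' missing values, rows sorted by (event_index, interval FIR < SIR < TIR),
#' UTF-8, LF line endings.  The file is meant to be hand-editable: re-read
#' it with [read_scores()] after manual correction.
#'
#' @param records Data frame of score records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(records, path) {
  records <- validate_scores(records)
  records <- dplyr::arrange(records, .data$event_index, .data$interval,
                            .data$rater)
  fmt <- function(x, digits) {
    ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  }
  lines <- paste(
    records$event_index, as.character(records$interval),
    fmt(records$trough_time_s, 3), fmt(records$trough_value_uS, 6),
    fmt(records$peak_time_s, 3), fmt(records$peak_value_uS, 6),
    fmt(records$amplitude_uS, 6), records$status, records$rater,
    sep = ","
  )
  con <- file(path, "wb")  # binary connection keeps LF endings everywhere
  on.exit(close(con))
  writeLines(c(paste(score_cols(), collapse = ","), lines), con, sep = "\n")
  invisible(path)
}

#' Read an annotation CSV back into score records
#'
#' @param path Path to a CSV produced by [write_scores()] (possibly edited).
#' @return A validated tibble of score records.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "scr_config_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    event_index = readr::col_integer(),
    interval = readr::col_character(),
    trough_time_s = readr::col_double(),
    trough_value_uS = readr::col_double(),
    peak_time_s = readr::col_double(),
    peak_value_uS = readr::col_double(),
    amplitude_uS = readr::col_double(),
    status = readr::col_character(),
    rater = readr::col_character()
  ), progress = FALSE)
  if (!identical(names(df), score_cols())) {
    abort(sprintf("Annotation header mismatch in %s; expected: %s",
                  basename(path), paste(score_cols(), collapse = ",")),
          class = "scr_parse_error")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed cell(s) in %s at row/col: %s", basename(path),
                  paste(sprintf("%d/%d", probs$row, probs$col), collapse = "; ")),
          class = "scr_parse_error")
  }
  validate_scores(df)
}
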