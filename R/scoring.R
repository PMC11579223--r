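#' Interval-scoring configuration
#'
#' Defines the detection threshold and the three latency windows on the
#' trial timeline: FIR (first interval response, orienting) with onsets 1-4 s
#' after CS onset; SIR (second interval, anticipatory) 4-7 s after CS onset;
#' TIR (third interval, US-related) 1-4 s after CS offset.  Windows are
#' half-open `[start, end)`: an onset exactly on a boundary belongs to the
#' later interval.
#'
#' @param threshold_uS Detection threshold ("delta") in uS: a peak is only
#'   confirmed if it stands at least this far above its flanking troughs,
#'   and vice versa.  Default 0.02.
#' @param cs_duration_s CS duration in seconds (default 6); anchors the TIR
#'   window to CS offset.
#' @param fir_window_s,sir_window_s Length-2 vectors, seconds after CS
#'   onset.  Defaults `c(1, 4)` and `c(4, 7)`.
#' @param tir_window_s Length-2 vector, seconds after CS *offset*.  Default
#'   `c(1, 4)`.
#' @param peak_horizon_s How far past a window's end the matching peak may
#'   fall (the response must *onset* in the window but may complete after
#'   it).  Default 4.
#' @return A list of class `scr_interval_config` with resolved absolute
#'   windows (`windows`: tibble of interval/start_s/end_s relative to CS
#'   onset).
#' @export
interval_config <- function(threshold_uS = 0.02, cs_duration_s = 6,
                            fir_window_s = c(1, 4), sir_window_s = c(4, 7),
                            tir_window_s = c(1, 4), peak_horizon_s = 4) {
  if (threshold_uS <= 0) {
    abort("`threshold_uS` must be positive.", class = "scr_validation_error")
  }
  if (peak_horizon_s < 0) {
    abort("`peak_horizon_s` must be >= 0.", class = "scr_validation_error")
  }
  windows <- tibble(
    interval = factor(interval_levels(), levels = interval_levels()),
    start_s = c(fir_window_s[1], sir_window_s[1], cs_duration_s + tir_window_s[1]),
    end_s = c(fir_window_s[2], sir_window_s[2], cs_duration_s + tir_window_s[2])
  )
  if (any(windows$end_s <= windows$start_s) ||
      any(diff(windows$start_s) <= 0) ||
      windows$start_s[2] < windows$end_s[1] ||
      windows$start_s[3] < windows$end_s[2]) {
    abort("Latency windows must be non-overlapping and ordered FIR < SIR < TIR.",
          class = "scr_validation_error")
  }
  structure(list(threshold_uS = threshold_uS, cs_duration_s = cs_duration_s,
                 peak_horizon_s = peak_horizon_s, windows = windows),
            class = "scr_interval_config")
}

#' Threshold-validated local extrema of a series
#'
#' Single left-to-right scan tracking the running extremum (delta-prominence
#' walker): a peak is confirmed once the series drops at least `threshold`
#' below the running maximum, a trough once it rises at least `threshold`
#' above the running minimum -- but a trough only becomes definitive once a
#' subsequent peak is confirmed (a rise of delta alone is not a peak), so a
#' monotone or flat series yields an empty table.  Confirmed extrema
#' alternate.  The series' first sample may anchor the first extremum;
#' after the scan the pending final extremum is emitted unconfirmed
#' (`confirmed = FALSE`) when at least one confirmed extremum precedes it.
#'
#' @param values Numeric series.
#' @param threshold Validation threshold (uS).
#' @return Tibble with columns `kind` ("peak"/"trough"), `idx` (1-based),
#'   `value`, `confirmed`.
#' @export
find_extrema <- function(values, threshold) {
  n <- length(values)
  kinds <- character(0); idxs <- integer(0); vals <- numeric(0)
  if (n < 3) {
    return(tibble(kind = kinds, idx = idxs, value = vals, confirmed = logical(0)))
  }
  mn <- mx <- values[1]; mnpos <- mxpos <- 1L
  mode <- 0L  # 0 unknown, 1 looking for a peak, -1 looking for a trough
  # A trough is only confirmed by a subsequent confirmed peak, so troughs
  # are held pending until their peak's delta-drop arrives (a mere rise of
  # delta is not a peak: a monotone ramp has no extrema).  Peaks keep the
  # first sample of a plateau, troughs the last -- the last sample at the
  # minimum before a rise is the response onset.
  pend_trough <- NULL
  for (i in 2:n) {
    v <- values[i]
    if (v > mx) { mx <- v; mxpos <- i }
    if (v <= mn) { mn <- v; mnpos <- i }
    peak_hit <- mode != -1L && v <= mx - threshold
    trough_hit <- mode != 1L && v >= mn + threshold
    if (peak_hit && trough_hit) {  # direction ambiguous: earlier extremum first
      if (mxpos <= mnpos) trough_hit <- FALSE else peak_hit <- FALSE
    }
    if (peak_hit) {
      if (!is.null(pend_trough)) {
        kinds <- c(kinds, "trough"); idxs <- c(idxs, pend_trough$idx)
        vals <- c(vals, pend_trough$value)
        pend_trough <- NULL
      }
      kinds <- c(kinds, "peak"); idxs <- c(idxs, mxpos); vals <- c(vals, mx)
      mn <- v; mnpos <- i; mode <- -1L
    } else if (trough_hit) {
      pend_trough <- list(idx = mnpos, value = mn)
      mx <- v; mxpos <- i; mode <- 1L
    }
  }
  confirmed <- rep(TRUE, length(kinds))
  if (length(kinds) > 0 && mode == -1L) {  # trailing trough after last peak
    kinds <- c(kinds, "trough"); idxs <- c(idxs, mnpos); vals <- c(vals, mn)
    confirmed <- c(confirmed, FALSE)
  } else if (length(kinds) > 0 && mode == 1L && !is.null(pend_trough)) {
    kinds <- c(kinds, "trough"); idxs <- c(idxs, pend_trough$idx)
    vals <- c(vals, pend_trough$value)
    confirmed <- c(confirmed, FALSE)
  }
  tibble(kind = kinds, idx = idxs, value = vals, confirmed = confirmed)
}

# Left-flank validation for a trough at i: walking left, an anchor sample
# >= x[i] + delta must appear before any sample strictly below x[i]; the
# series start counts as an anchor (a response may already be rising when
# the segment begins).
trough_left_ok <- function(x, i, delta) {
  if (i == 1L) return(TRUE)
  for (k in (i - 1L):1L) {
    if (x[k] < x[i]) return(FALSE)
    if (x[k] >= x[i] + delta) return(TRUE)
  }
  TRUE
}

# Right-flank validation for a peak at j: a genuine subsequent drop of delta
# is required before any sample strictly above x[j]; reaching the end of the
# usable data does NOT confirm (a still-rising edge is not a peak).
peak_right_ok <- function(x, j, delta, n_eff) {
  if (j >= n_eff) return(FALSE)
  for (k in (j + 1L):n_eff) {
    if (x[k] > x[j]) return(FALSE)
    if (x[k] <= x[j] - delta) return(TRUE)
  }
  FALSE
}

#' Score one latency window of a segment
#'
#' Finds the threshold-validated (trough, subsequent peak) pair with maximal
#' trough-to-peak amplitude among pairs whose trough time falls in
#' `[start_s, end_s)` (relative to the segment start).  The peak may occur
#' up to `peak_horizon_s` past the window end but never beyond the segment
#' or the next event onset.  Strictly between trough and peak the trace
#' must stay strictly above the trough value and strictly below the peak
#' value, so the trough is the last sample at the pre-rise minimum (the
#' response onset) and the peak the first sample at the maximum.  Ties in
#' amplitude go to the earliest trough, then the earliest peak.  If no pair
#' qualifies the trial
#' is a non-response and a `status = "zero"` record (amplitude 0) is
#' returned; a window that falls outside truncated data yields
#' `status = "missing_artifact"`.
#'
#' @param values Segment samples (filtered, at `fs`).
#' @param fs Segment rate (Hz).
#' @param window Length-2 vector `c(start_s, end_s)` relative to segment
#'   start.
#' @param cfg An [interval_config()].
#' @param interval Interval label for the output record.
#' @param event_index Trial number for the output record.
#' @param t0_s Segment start in session time; reported times are absolute.
#' @param next_onset_s Onset of the next event relative to segment start
#'   (`Inf` if none); the search never crosses it.
#' @param rater Rater label.
#' @return A one-row score record tibble.
#' @export
score_interval <- function(values, fs, window, cfg = interval_config(),
                           interval = "FIR", event_index = 1L, t0_s = 0,
                           next_onset_s = Inf, rater = "auto") {
  delta <- cfg$threshold_uS
  n <- length(values)
  n_eff <- min(n, floor(next_onset_s * fs + 1e-9))
  if (window[2] > n / fs + 1e-9) {  # window extends past available data
    return(new_score_record(event_index, interval, status = "missing_artifact",
                            amplitude_uS = NA_real_, rater = rater))
  }
  t_of <- function(i) (i - 1) / fs
  in_win <- which(t_of(seq_len(n_eff)) >= window[1] - 1e-9 &
                    t_of(seq_len(n_eff)) < window[2] - 1e-9)
  peak_limit_t <- window[2] + cfg$peak_horizon_s
  peak_ok_memo <- rep(NA, n_eff)
  best <- NULL
  for (i in in_win) {
    if (i > 1L && values[i - 1L] < values[i]) next  # not a local minimum
    if (!trough_left_ok(values, i, delta)) next
    if (i >= n_eff) next
    runmax <- -Inf  # strict interior: trough is the last sample at the
    for (j in (i + 1L):n_eff) {  # minimum, peak the first at the maximum
      if (values[j] <= values[i]) break         # envelope broken below
      is_new_max <- values[j] > runmax
      if (is_new_max) runmax <- values[j]
      if (is_new_max &&
          values[j] - values[i] >= delta &&
          t_of(j) <= peak_limit_t + 1e-9) {
        if (is.na(peak_ok_memo[j])) {
          peak_ok_memo[j] <- peak_right_ok(values, j, delta, n_eff)
        }
        if (peak_ok_memo[j]) {
          amp <- values[j] - values[i]
          if (is.null(best) || amp > best$amp) {
            best <- list(i = i, j = j, amp = amp)
          }
        }
      }
    }
  }
  if (is.null(best)) {
    return(new_score_record(event_index, interval, status = "zero",
                            rater = rater))
  }
  new_score_record(event_index, interval,
                   trough_time_s = t0_s + t_of(best$i),
                   trough_value_uS = values[best$i],
                   peak_time_s = t0_s + t_of(best$j),
                   peak_value_uS = values[best$j],
                   amplitude_uS = best$amp, status = "auto", rater = rater)
}

#' Score a whole session
#'
#' Preprocesses the session (high-pass filter, per-trial segmentation,
#' bin-mean resampling) and scores the FIR, SIR and TIR windows of every
#' event.  Deterministic: identical inputs give identical outputs.
#'
#' @param session An [scr_session()].
#' @param preproc A [preproc_config()].
#' @param cfg An [interval_config()].
#' @param rater Rater label attached to every record.
#' @return A validated `scr_scores` tibble with 3 rows per event.
#' @export
score_session <- function(session, preproc = preproc_config(),
                          cfg = interval_config(), rater = "auto") {
  segs <- preprocess_session(session, preproc)
  if (nrow(segs) == 0) {
    abort("Session has no events to score.", class = "scr_validation_error")
  }
  recs <- purrr::pmap(
    list(segs$event_index, segs$t0_s, segs$next_onset_s, segs$values),
    function(event_index, t0_s, next_onset_s, values) {
      purrr::pmap(
        list(as.character(cfg$windows$interval), cfg$windows$start_s,
             cfg$windows$end_s),
        function(interval, start_s, end_s) {
          score_interval(values, segs$fs[1], c(start_s, end_s), cfg,
                         interval = interval, event_index = event_index,
                         t0_s = t0_s, next_onset_s = next_onset_s,
                         rater = rater)
        }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  validate_scores(recs)
}

#' Apply manual overrides to score records
#'
#' The programmatic counterpart of dragging markers in an interactive
#' scorer.  Each override row targets one (event_index, interval) record
#' (and rater, when the records carry several).  Supplying a `status` of
#' `"zero"` or `"missing_artifact"` replaces the record with a nulled one;
#' otherwise new trough/peak coordinates must be supplied and the record
#' becomes `status = "adjusted"` with the amplitude recomputed.
#'
#' @param records A score table (as from [score_session()]).
#' @param overrides Data frame with columns `event_index`, `interval`, and
#'   either `status` or the four coordinate columns `trough_time_s`,
#'   `trough_value_uS`, `peak_time_s`, `peak_value_uS` (optionally `rater`).
#' @return The revalidated score table.
#' @export
apply_overrides <- function(records, overrides) {
  records <- as_tibble(records)
  overrides <- as_tibble(overrides)
  for (r in seq_len(nrow(overrides))) {
    ov <- overrides[r, ]
    hit <- records$event_index == ov$event_index &
      as.character(records$interval) == as.character(ov$interval)
    if ("rater" %in% names(ov) && !is.na(ov$rater)) {
      hit <- hit & records$rater == ov$rater
    }
    if (!any(hit)) {
      abort(sprintf("Override targets missing record: event %d, interval %s.",
                    ov$event_index, as.character(ov$interval)),
            class = "scr_validation_error")
    }
    w <- which(hit)
    if ("status" %in% names(ov) && !is.na(ov$status) &&
        ov$status %in% c("zero", "missing_artifact")) {
      records$status[w] <- ov$status
      records$trough_time_s[w] <- NA_real_
      records$trough_value_uS[w] <- NA_real_
      records$peak_time_s[w] <- NA_real_
      records$peak_value_uS[w] <- NA_real_
      records$amplitude_uS[w] <- if (ov$status == "zero") 0 else NA_real_
    } else {
      needed <- c("trough_time_s", "trough_value_uS", "peak_time_s",
                  "peak_value_uS")
      if (!all(needed %in% names(ov)) || anyNA(ov[needed])) {
        abort("Coordinate override needs trough_time_s, trough_value_uS, peak_time_s, peak_value_uS.",
              class = "scr_validation_error")
      }
      if (ov$trough_time_s >= ov$peak_time_s) {
        abort(sprintf("Override for event %d %s has trough at/after peak.",
                      ov$event_index, as.character(ov$interval)),
              class = "scr_validation_error")
      }
      amp <- ov$peak_value_uS - ov$trough_value_uS
      if (amp <= 0) {
        abort(sprintf("Override for event %d %s implies non-positive amplitude.",
                      ov$event_index, as.character(ov$interval)),
              class = "scr_validation_error")
      }
      records$trough_time_s[w] <- ov$trough_time_s
      records$trough_value_uS[w] <- ov$trough_value_uS
      records$peak_time_s[w] <- ov$peak_time_s
      records$peak_value_uS[w] <- ov$peak_value_uS
      records$amplitude_uS[w] <- amp
      records$status[w] <- "adjusted"
    }
  }
  validate_scores(records)
}
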