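#' Preprocessing configuration
#'
#' Parameters for the fixed preprocessing chain: linear-phase high-pass
#' filtering of the raw trace, segmentation into per-trial windows, and
#' bin-mean resampling to the scoring rate.
#'
#' @param hp_cutoff_hz High-pass cutoff (-6 dB point) in Hz. Default 0.5,
#'   which removes tonic level and slow drift while passing the phasic
#'   response.
#' @param hp_numtaps Filter length in taps at 1000 Hz, odd. Default 3001
#'   (a 3 s Hamming window), long enough that 0.05 Hz drift is attenuated
#'   below 0.1 while 2 Hz content passes within 5%; scaled proportionally
#'   for other sampling rates.
#' @param target_fs_hz Scoring rate after bin-mean resampling. Default 50.
#' @param segment_len_s Segment length L in seconds following each event.
#'   Default 18: the last permissible peak time is the TIR window end
#'   (CS 6 s + 4 s) plus the 4 s peak-search horizon = 14 s, and a peak is
#'   only confirmed once the trace has fallen back below it by the
#'   detection threshold, which needs a few seconds of decay tail beyond
#'   the peak.  Overlap with the next trial is excluded at scoring time by
#'   the next-event clip, so a generous L costs nothing.
#' @param order Either `"filter_first"` (filter the full-rate trace, then
#'   segment, then resample; the default) or `"resample_first"`.
#' @return A list of class `scr_preproc_config`.
#' @export
preproc_config <- function(hp_cutoff_hz = 0.5, hp_numtaps = 3001,
                           target_fs_hz = 50, segment_len_s = 18,
                           order = c("filter_first", "resample_first")) {
  order <- match.arg(order)
  if (hp_numtaps %% 2 != 1 || hp_numtaps < 3) {
    abort("`hp_numtaps` must be an odd integer >= 3.", class = "scr_validation_error")
  }
  if (!(hp_cutoff_hz > 0 && hp_cutoff_hz < target_fs_hz / 2)) {
    abort("Need 0 < hp_cutoff_hz < target_fs_hz / 2.", class = "scr_validation_error")
  }
  if (segment_len_s <= 0) {
    abort("`segment_len_s` must be positive.", class = "scr_validation_error")
  }
  structure(list(hp_cutoff_hz = hp_cutoff_hz, hp_numtaps = hp_numtaps,
                 target_fs_hz = target_fs_hz, segment_len_s = segment_len_s,
                 order = order),
            class = "scr_preproc_config")
}

# Tap count for a given rate: the default is expressed at 1000 Hz and scaled
# so the filter's impulse-response duration (hence its transition band in Hz)
# is rate-independent.
hp_taps_at <- function(cfg, fs) {
  n <- round(cfg$hp_numtaps * fs / 1000)
  n <- max(3L, as.integer(n))
  if (n %% 2 == 0) n <- n + 1L
  n
}

#' High-pass filter a skin-conductance trace
#'
#' Windowed-sinc FIR high-pass (Hamming window) applied with zero net delay:
#' the trace is reflect-padded by one filter length per side, convolved via
#' FFT, and the group delay of (numtaps - 1)/2 samples removed, so peak and
#' trough latencies are unbiased.  Output length equals input length and the
#' DC component is removed.
#'
#' @param sc Numeric trace (uS).
#' @param fs Sampling rate (Hz).
#' @param cfg A [preproc_config()].
#' @return Filtered numeric trace, same length as `sc`.
#' @export
highpass <- function(sc, fs, cfg = preproc_config()) {
  n_taps <- hp_taps_at(cfg, fs)
  if (length(sc) <= n_taps) {
    abort(sprintf(
      "Series (%d samples) must be longer than the filter (%d taps); use a shorter `hp_numtaps`.",
      length(sc), n_taps), class = "scr_validation_error")
  }
  h <- hp_taps(n_taps, cfg$hp_cutoff_hz, fs)
  n <- length(sc)
  left <- rev(sc[2:(n_taps + 1)])
  right <- rev(sc[(n - n_taps):(n - 1)])
  padded <- c(left, sc, right)
  y <- fft_conv(padded, h)
  delay <- (n_taps - 1) / 2
  y[(n_taps + delay + 1):(n_taps + delay + n)]
}

# Linear convolution via FFT, zero-padded to a power of two (plain
# stats::convolve transforms at awkward lengths and can be very slow).
fft_conv <- function(x, h) {
  L <- length(x) + length(h) - 1L
  n2 <- stats::nextn(L, 2)
  X <- stats::fft(c(x, numeric(n2 - length(x))))
  H <- stats::fft(c(h, numeric(n2 - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(L)] / n2
}

# Windowed-sinc high-pass tap sequence: ideal lowpass impulse response
# truncated by a symmetric Hamming window, normalized to unit DC gain and
# spectrally inverted (delta minus lowpass).  DC gain is therefore exactly
# zero and tonic level cannot leak through.  The design is written out in
# closed form, sampled from the continuous-time prototype, so taps at
# different sampling rates realize the same analog response (grid-based
# designs are rate-inconsistent at sub-Hz cutoffs).  The cutoff is the
# filter's -6 dB point.
hp_taps <- function(n_taps, cutoff_hz, fs) {
  m <- (n_taps - 1L) / 2L
  k <- seq_len(n_taps) - 1L - m
  lp <- ifelse(k == 0, 2 * cutoff_hz / fs, sin(2 * pi * cutoff_hz * k / fs) / (pi * k))
  w <- 0.54 + 0.46 * cos(2 * pi * k / (n_taps - 1))
  lp <- lp * w
  lp <- lp / sum(lp)
  h <- -lp
  h[m + 1L] <- h[m + 1L] + 1
  h
}

#' Resample a trace by contiguous time-bin means
#'
#' Output sample k is the mean of all input samples with timestamps in
#' [k/target_fs, (k+1)/target_fs); bins are defined on the time axis so
#' non-integer rate ratios work.  If `fs < target_fs` the series is
#' returned unchanged with a warning (no upsampling).
#'
#' @param sc Numeric trace.
#' @param fs Input rate (Hz).
#' @param target_fs Output rate (Hz).
#' @return Numeric trace at `target_fs`.
#' @export
resample_mean <- function(sc, fs, target_fs) {
  if (length(sc) == 0) {
    abort("Cannot resample an empty series.", class = "scr_validation_error")
  }
  if (fs < target_fs) {
    warn(sprintf("fs (%g Hz) below target (%g Hz); series returned unchanged.",
                 fs, target_fs))
    return(sc)
  }
  if (fs == target_fs) return(sc)
  bin <- floor((seq_along(sc) - 1) / fs * target_fs)
  as.numeric(rowsum(sc, bin) / tabulate(bin + 1L, nbins = max(bin) + 1L))
}

#' Segment a trace around event onsets
#'
#' Cuts one window of `segment_len_s` seconds starting at each event onset.
#' A window reaching past the end of the recording is truncated and flagged
#' (`truncated = TRUE`); downstream scoring turns latency windows that fall
#' outside truncated data into `missing_artifact` records.  Each segment
#' also records the onset of the next event (`next_onset_s`, relative to
#' its own start) so scoring never reads past the following trial.
#'
#' @param sc Numeric trace (already filtered and/or resampled as desired).
#' @param fs Rate of `sc` (Hz).
#' @param events Event table (`index`, `onset_s`, `label`).
#' @param cfg A [preproc_config()] (only `segment_len_s` is used here).
#' @return Tibble with one row per event: `event_index`, `label`, `t0_s`,
#'   `fs`, `truncated`, `next_onset_s`, and a list-column `values`.
#' @export
segment_trace <- function(sc, fs, events, cfg = preproc_config()) {
  n_out <- round(cfg$segment_len_s * fs)
  dur <- length(sc) / fs
  rows <- purrr::pmap(
    list(events$index, events$onset_s, events$label,
         dplyr::lead(events$onset_s, default = Inf)),
    function(index, onset, label, next_onset) {
      i0 <- round(onset * fs)  # 0-based sample of onset
      i1 <- min(i0 + n_out, length(sc))
      vals <- if (i1 > i0) sc[(i0 + 1):i1] else numeric(0)
      tibble(event_index = as.integer(index), label = label, t0_s = onset,
             fs = fs, truncated = length(vals) < n_out,
             next_onset_s = next_onset - onset, values = list(vals))
    })
  dplyr::bind_rows(rows)
}

#' Run the full preprocessing chain for a session
#'
#' @param session An [scr_session()].
#' @param cfg A [preproc_config()].
#' @return Segment tibble (see [segment_trace()]) at `target_fs_hz`.
#' @export
preprocess_session <- function(session, cfg = preproc_config()) {
  if (identical(cfg$order, "filter_first")) {
    filt <- highpass(session$sc, session$fs, cfg)
    segs <- segment_trace(filt, session$fs, session$events, cfg)
    segs$values <- purrr::map(segs$values, resample_mean,
                              fs = session$fs, target_fs = cfg$target_fs_hz)
    segs$truncated <- purrr::map_int(segs$values, length) <
      round(cfg$segment_len_s * cfg$target_fs_hz)
    segs$fs <- cfg$target_fs_hz
    segs
  } else {
    low <- resample_mean(session$sc, session$fs, cfg$target_fs_hz)
    filt <- highpass(low, cfg$target_fs_hz, cfg)
    segment_trace(filt, cfg$target_fs_hz, session$events, cfg)
  }
}
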