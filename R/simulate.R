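#' Simulation design for a differential fear-conditioning session
#'
#' Defines the paradigm (trial counts per phase, CS duration, jittered
#' inter-trial intervals) and the generative model for the skin-conductance
#' trace: biexponential SCR kernels of known amplitude at known onsets,
#' tonic level plus slow drift, Gaussian sensor noise, and occasional
#' step/spike artifacts.  The kernel and noise model are an emulation for
#' testing the scoring pipeline, not a calibrated physiological model.
#'
#' @param n_trials Named integer vector: trials *per CS* in each phase.
#'   Default `c(habituation = 4, acquisition = 8, extinction = 24)`.
#' @param cs_duration_s CS duration (s), default 6.
#' @param iti_range_s Inter-trial interval (CS offset to next CS onset)
#'   jitter range, default `c(10, 14)`.
#' @param fs Sampling rate (Hz), default 1000.
#' @param amp_mean_uS Mean injected kernel amplitudes per interval for a
#'   CS+ trial, default `c(FIR = 0.30, SIR = 0.20, TIR = 0.40)`.
#' @param cs_minus_gain Multiplier on CS- amplitudes during acquisition and
#'   extinction, default 0.6 (differential responding).
#' @param habituation_tau Exponential habituation time constant in trials
#'   (amplitudes shrink as `exp(-(trial - 1) / tau)` per CS), default 8.
#' @param amp_sigma Lognormal trial-to-trial variability (sdlog), default
#'   0.25.
#' @param response_prob Probability a given trial x interval produces a
#'   response at all, default 0.85 (non-responses have true amplitude 0).
#' @param onset_margin_s Responses onset at least this far inside their
#'   latency window, default 0.2 (keeps programmed onsets away from the
#'   half-open boundaries).
#' @param kernel_rise_s,kernel_decay_s Kernel time constants (s), defaults
#'   0.75 and 3.
#' @param tonic_uS Tonic skin-conductance level, default 5.
#' @param drift_amp_uS Amplitude of the slow sinusoidal drift, default 0.5.
#' @param noise_sd_uS Gaussian noise SD, default 0.005.
#' @param artifact_rate_per_min Rate of step/spike artifacts, default 0.3.
#' @param lead_in_s,tail_s Quiet recording before the first and after the
#'   last trial, defaults 20 and 20.
#' @param seed Integer seed; the seed fully determines the session.
#' @return A list of class `scr_sim_design`.
#' @export
sim_design <- function(n_trials = c(habituation = 4, acquisition = 8,
                                    extinction = 24),
                       cs_duration_s = 6, iti_range_s = c(10, 14), fs = 1000,
                       amp_mean_uS = c(FIR = 0.30, SIR = 0.20, TIR = 0.40),
                       cs_minus_gain = 0.6, habituation_tau = 8,
                       amp_sigma = 0.25, response_prob = 0.85,
                       onset_margin_s = 0.2, kernel_rise_s = 0.75,
                       kernel_decay_s = 3, tonic_uS = 5, drift_amp_uS = 0.5,
                       noise_sd_uS = 0.005, artifact_rate_per_min = 0.3,
                       lead_in_s = 20, tail_s = 20, seed = 1L) {
  stopifnot(all(n_trials > 0), cs_duration_s > 0, fs > 0,
            iti_range_s[1] <= iti_range_s[2], iti_range_s[1] > 0,
            kernel_rise_s > 0, kernel_rise_s < kernel_decay_s,
            response_prob >= 0, response_prob <= 1, noise_sd_uS >= 0,
            artifact_rate_per_min >= 0)
  structure(as.list(environment()), class = "scr_sim_design")
}

#' Biexponential SCR kernel
#'
#' Difference of exponentials, zero before onset, peak-normalized and
#' scaled so the series maximum equals `amplitude`: the canonical gradual
#' rise to a peak followed by a long decay tail.
#'
#' @param t Numeric time axis (s).
#' @param t_onset Response onset (s).
#' @param amplitude Peak amplitude (uS, >= 0).
#' @param rise_s,decay_s Time constants (s), rise < decay.
#' @return Numeric series along `t`.
#' @export
scr_kernel <- function(t, t_onset, amplitude, rise_s = 0.75, decay_s = 3) {
  stopifnot(amplitude >= 0, rise_s > 0, rise_s < decay_s)
  if (amplitude == 0) return(numeric(length(t)))
  tt <- t - t_onset
  k <- ifelse(tt < 0, 0, exp(-tt / decay_s) - exp(-tt / rise_s))
  tp <- log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
  amplitude * k / (exp(-tp / decay_s) - exp(-tp / rise_s))
}

#' Time of the kernel peak relative to onset
#' @param rise_s,decay_s Kernel time constants (s).
#' @return Peak latency in seconds.
#' @export
scr_kernel_peak_time <- function(rise_s = 0.75, decay_s = 3) {
  log(decay_s / rise_s) * rise_s * decay_s / (decay_s - rise_s)
}

# Trial schedule: phases in order, CS+ and CS- trials shuffled within
# phase, onsets snapped to the 50 Hz scoring grid so segment bins align
# with the full-trace bins.
sim_schedule <- function(design, phases) {
  trial_len <- function() design$cs_duration_s +
    runif(1, design$iti_range_s[1], design$iti_range_s[2])
  rows <- list()
  t_cursor <- design$lead_in_s
  counts <- c("CS+" = 0L, "CS-" = 0L)
  for (ph in phases) {
    k <- design$n_trials[[ph]]
    conds <- sample(rep(c("CS+", "CS-"), k))
    for (cond in conds) {
      counts[cond] <- counts[cond] + 1L
      onset <- round(t_cursor * 50) / 50
      rows[[length(rows) + 1L]] <- tibble(
        phase = ph, condition = cond, onset_s = onset,
        trial_of_cs = counts[[cond]])
      t_cursor <- t_cursor + trial_len()
    }
  }
  sched <- dplyr::bind_rows(rows)
  sched$event_index <- seq_len(nrow(sched))
  sched
}

sim_condition_gain <- function(phase, condition, design) {
  dplyr::case_when(
    phase == "habituation" ~ 1,
    phase == "acquisition" & condition == "CS+" ~ 1,
    phase == "acquisition" ~ design$cs_minus_gain,
    condition == "CS+" ~ design$cs_minus_gain +
      (1 - design$cs_minus_gain) * 0.5,  # partial extinction retention
    TRUE ~ design$cs_minus_gain
  )
}

#' Simulate a fear-conditioning recording session
#'
#' Builds the trial schedule, draws per-trial response amplitudes and
#' onsets, sums SCR kernels over tonic level, drift, noise and artifacts,
#' and returns both the session and its ground truth.  The truth table
#' carries the injected kernel amplitude (`amp_injected_uS`) and, for
#' end-to-end comparisons, `amplitude_true_uS`: the trough-to-peak reading
#' an ideal scorer would take from the noise-free trace after the standard
#' preprocessing in `preproc` (the high-pass filter substantially
#' attenuates and sharpens the kernel, so the two differ by design).
#'
#' @param design An [sim_design()].
#' @param phases Which phases to include, in order.  Default
#'   `c("habituation", "acquisition")` (recorded as one file in the
#'   emulated paradigm); use `"extinction"` for the second recording.
#' @param preproc The [preproc_config()] used to compute `amplitude_true_uS`.
#' @param scoring Optional [interval_config()]; its detection threshold is
#'   used to classify each true response as `detectable` (amplitude and
#'   post-peak confirmation drop both clear the threshold with 10% margin),
#'   `borderline` (within 5% of the threshold on either quantity -- the
#'   ambiguous band at 50 Hz discretization), or undetectable.  Defaults to
#'   the standard configuration at the design's CS duration.
#' @return List with elements `session` (an [scr_session()]) and `truth`
#'   (tibble: one row per trial x interval, with measured truth columns
#'   `amplitude_true_uS`, `trough_time_s`, `peak_time_s`,
#'   `confirm_drop_uS`, `trough_anchor_uS`, `detectable`, `borderline`).
#' @export
simulate_session <- function(design = sim_design(),
                             phases = c("habituation", "acquisition"),
                             preproc = preproc_config(),
                             scoring = NULL) {
  set.seed(design$seed)
  stopifnot(all(phases %in% names(design$n_trials)))
  sched <- sim_schedule(design, phases)
  windows <- interval_config(cs_duration_s = design$cs_duration_s)$windows
  margin <- design$onset_margin_s

  truth <- tidyr::crossing(sched, interval = windows$interval) |>
    dplyr::left_join(windows, by = "interval") |>
    dplyr::arrange(.data$event_index, .data$interval)
  n_ti <- nrow(truth)
  responds <- runif(n_ti) < design$response_prob
  gain <- sim_condition_gain(truth$phase, truth$condition, design)
  hab <- exp(-(truth$trial_of_cs - 1) / design$habituation_tau)
  base <- design$amp_mean_uS[as.character(truth$interval)] * gain * hab
  amp <- ifelse(responds,
                stats::rlnorm(n_ti, meanlog = log(base) - design$amp_sigma^2 / 2,
                              sdlog = design$amp_sigma),
                0)
  onset_rel <- runif(n_ti, truth$start_s + margin, truth$end_s - margin)
  onset_rel <- round(onset_rel * 50) / 50  # snap to the scoring grid
  truth$amp_injected_uS <- amp
  truth$onset_rel_s <- ifelse(amp > 0, onset_rel, NA_real_)
  truth$onset_abs_s <- truth$onset_s + truth$onset_rel_s

  dur <- max(sched$onset_s) + design$cs_duration_s + design$tail_s
  n <- round(dur * design$fs)
  t <- (seq_len(n) - 1) / design$fs
  clean <- numeric(n)
  resp_rows <- which(truth$amp_injected_uS > 0)
  for (r in resp_rows) {
    on <- truth$onset_abs_s[r]
    i0 <- round(on * design$fs) + 1
    i1 <- min(n, i0 + round(30 * design$fs))  # kernel support: 30 s tail
    seg_t <- t[i0:i1]
    clean[i0:i1] <- clean[i0:i1] +
      scr_kernel(seg_t, on, truth$amp_injected_uS[r],
                 design$kernel_rise_s, design$kernel_decay_s)
  }

  drift <- design$drift_amp_uS *
    (sin(2 * pi * t / 97 + runif(1, 0, 2 * pi)) +
       0.5 * sin(2 * pi * t / 211 + runif(1, 0, 2 * pi)))
  noise <- if (design$noise_sd_uS > 0) rnorm(n, 0, design$noise_sd_uS) else 0
  artifact <- sim_artifacts(n, design)
  sc <- design$tonic_uS + drift + clean + noise + artifact
  resp_chan <- sin(2 * pi * t * 0.25) +
    if (design$noise_sd_uS > 0) rnorm(n, 0, 0.05) else 0

  session <- scr_session(
    sc = sc, fs = design$fs,
    events = tibble(index = sched$event_index, onset_s = sched$onset_s,
                    label = sched$condition),
    resp = resp_chan,
    meta = list(simulated = TRUE, phases = paste(phases, collapse = "+"),
                seed = design$seed))

  truth <- measure_truth(truth, clean, design, preproc, scoring)
  list(session = session, truth = truth[c(
    "event_index", "phase", "condition", "interval", "onset_s",
    "amp_injected_uS", "onset_rel_s", "onset_abs_s",
    "amplitude_true_uS", "trough_time_s", "peak_time_s",
    "confirm_drop_uS", "trough_anchor_uS", "detectable", "borderline")])
}

# Step and spike artifacts at a Poisson rate per minute.
sim_artifacts <- function(n, design) {
  out <- numeric(n)
  dur_min <- n / design$fs / 60
  k <- rpois(1, design$artifact_rate_per_min * dur_min)
  if (k == 0) return(out)
  at <- sort(runif(k, 0, n / design$fs))
  for (a in at) {
    i0 <- round(a * design$fs) + 1
    size <- sample(c(-1, 1), 1) * runif(1, 0.2, 1)
    if (runif(1) < 0.5) {            # step with a 0.5 s ramp
      ramp <- round(0.5 * design$fs)
      i1 <- min(n, i0 + ramp)
      out[i0:i1] <- out[i0:i1] + size * seq(0, 1, length.out = i1 - i0 + 1)
      if (i1 < n) out[(i1 + 1):n] <- out[(i1 + 1):n] + size
    } else {                          # fast spike, 0.3 s decay
      i1 <- min(n, i0 + round(2 * design$fs))
      tt <- (seq(i0, i1) - i0) / design$fs
      out[i0:i1] <- out[i0:i1] + size * exp(-tt / 0.3)
    }
  }
  out
}

# Ideal-scorer reading of the clean trace after standard preprocessing.
# For each programmed response: the local peak near the known onset is
# found first; the trough is the deepest point between the latency-window
# start and that peak (the high-pass undershoot of an earlier response may
# place it before the programmed onset); the peak is then extended along
# the envelope -- as long as the trace stays above the trough -- up to the
# window end plus peak horizon, because a rise that runs without a
# threshold-deep dip into the next response's higher peak reads as one
# merged trough-to-peak event.  Computed by direct argmin/argmax scans on
# the whole-session trace: no segmentation, no extremum walker, no pair
# enumeration.
measure_truth <- function(truth, clean, design, preproc, scoring = NULL) {
  scoring <- scoring %||% interval_config(cs_duration_s = design$cs_duration_s)
  delta <- scoring$threshold_uS
  f50 <- resample_mean(highpass(clean, design$fs, preproc),
                       design$fs, preproc$target_fs_hz)
  tfs <- preproc$target_fs_hz
  t50 <- (seq_along(f50) - 1) / tfs
  ev_onsets <- sort(unique(truth$onset_s))
  next_event <- stats::setNames(c(ev_onsets[-1], Inf), ev_onsets)
  truth$amplitude_true_uS <- 0
  truth$trough_time_s <- NA_real_
  truth$peak_time_s <- NA_real_
  truth$confirm_drop_uS <- NA_real_
  truth$trough_anchor_uS <- NA_real_
  for (r in which(truth$amp_injected_uS > 0)) {
    on <- truth$onset_abs_s[r]
    vis_end <- min(truth$onset_s[r] + preproc$segment_len_s,
                   next_event[[as.character(truth$onset_s[r])]],
                   t50[length(t50)])
    later <- truth$onset_abs_s[truth$event_index == truth$event_index[r] &
                                 truth$amp_injected_uS > 0]
    later <- later[later > on]
    hi <- min(on + 3, if (length(later)) min(later) else Inf, vis_end)
    pk_win <- which(t50 >= on & t50 <= hi)
    jp <- pk_win[which.max(f50[pk_win])]
    win_lo <- truth$onset_s[r] + truth$start_s[r]
    tr_win <- which(t50 >= win_lo & t50 <= t50[jp])
    jt <- tr_win[max(which(f50[tr_win] == min(f50[tr_win])))]
    # Extend the peak along the envelope: the latest permissible peak time
    # is the window end plus the horizon; the envelope ends where the
    # trace first falls below the trough.
    reach_end <- min(truth$onset_s[r] + truth$end_s[r] +
                       scoring$peak_horizon_s, vis_end)
    reach <- which(t50 > t50[jt] & t50 <= reach_end)
    below <- which(f50[reach] <= f50[jt])
    if (length(below)) reach <- reach[seq_len(below[1] - 1)]
    if (length(reach)) jp <- reach[which.max(f50[reach])]
    truth$amplitude_true_uS[r] <- f50[jp] - f50[jt]
    truth$trough_time_s[r] <- t50[jt]
    truth$peak_time_s[r] <- t50[jp]
    # Confirmation drop: how far the trace falls back below the peak before
    # it first exceeds the peak again, within the data a scorer can see
    # (the segment, clipped at the next event).  The scoring rule only
    # confirms a peak once this drop reaches the detection threshold.
    look <- which(t50 > t50[jp] & t50 <= vis_end)
    exceed <- which(f50[look] > f50[jp])
    if (length(exceed)) look <- look[seq_len(exceed[1] - 1)]
    truth$confirm_drop_uS[r] <-
      if (length(look)) f50[jp] - min(f50[look]) else 0
    # Trough left-flank anchor: how far the trace rises above the trough,
    # walking left, before first going below it.  The scoring rule needs a
    # threshold-high anchor (or the segment start, which always anchors).
    lft <- which(t50 >= truth$onset_s[r] & t50 < t50[jt])
    lower <- which(f50[lft] < f50[jt])
    anchored_by_start <- length(lower) == 0
    if (!anchored_by_start) lft <- lft[lft > lft[max(lower)]]
    truth$trough_anchor_uS[r] <- if (anchored_by_start) {
      Inf
    } else if (length(lft)) {
      max(f50[lft]) - f50[jt]
    } else 0
  }
  # Detection-boundary classification: a response is flagged detectable
  # when both its amplitude and its confirmation drop clear the threshold
  # with 10% margin; one whose amplitude falls 5% short is undetectable by
  # construction; the band in between is genuinely ambiguous at 50 Hz
  # discretization and is asserted neither way.
  amp_ratio <- truth$amplitude_true_uS / delta
  drop_ratio <- truth$confirm_drop_uS / delta
  anchor_ratio <- truth$trough_anchor_uS / delta
  truth$detectable <- truth$amp_injected_uS > 0 &
    amp_ratio >= 1.1 & !is.na(drop_ratio) & drop_ratio >= 1.1 &
    !is.na(anchor_ratio) & anchor_ratio >= 1.1
  truth$borderline <- truth$amp_injected_uS > 0 & !truth$detectable &
    amp_ratio >= 0.95
  truth
}

#' Simulate a rater re-scoring ground truth
#'
#' Perturbs the true amplitudes with Gaussian rater noise and randomly
#' marks trials missing/artifact, packaging the result as score records.
#' Drives the agreement statistics with a known expected ICC:
#' `sigma_targets^2 / (sigma_targets^2 + sigma_noise^2)` for raters that
#' share the truth.
#'
#' @param truth Truth tibble from [simulate_session()].
#' @param rater_noise_sd Gaussian noise SD on amplitudes (uS).
#' @param miss_rate Probability a trial x interval is marked
#'   missing/artifact.
#' @param seed Integer seed.
#' @param rater Rater label.
#' @param truth_col Which truth column to perturb; default
#'   `"amplitude_true_uS"`.
#' @return A validated `scr_scores` tibble.
#' @export
simulate_rater <- function(truth, rater_noise_sd = 0, miss_rate = 0,
                           seed = 1L, rater = "sim",
                           truth_col = "amplitude_true_uS") {
  stopifnot(rater_noise_sd >= 0, miss_rate >= 0, miss_rate <= 1)
  set.seed(seed)
  n <- nrow(truth)
  amp <- truth[[truth_col]] + rnorm(n, 0, rater_noise_sd)
  missing <- runif(n) < miss_rate
  recs <- purrr::pmap(
    list(truth$event_index, as.character(truth$interval), amp,
         truth$trough_time_s, truth$peak_time_s, missing),
    function(ev, interval, a, tt, pt, miss) {
      if (miss) {
        new_score_record(ev, interval, status = "missing_artifact",
                         amplitude_uS = NA_real_, rater = rater)
      } else if (is.na(tt) || a <= 0) {
        new_score_record(ev, interval, status = "zero", rater = rater)
      } else {
        new_score_record(ev, interval, trough_time_s = tt,
                         trough_value_uS = 0, peak_time_s = pt,
                         peak_value_uS = a, amplitude_uS = a,
                         status = "auto", rater = rater)
      }
    }) |> dplyr::bind_rows()
  validate_scores(recs)
}

#' Write a simulated session to disk
#'
#' Emits either the plain-text CSV session format (columns `SC`, `Resp`,
#' `Marker`) or a classic v5 MAT-file (variables `SC`, `Resp`, `Marker`,
#' `fs`), both round-tripped by [read_session()].
#'
#' @param session An [scr_session()].
#' @param path Output path; format chosen by extension (`.mat` vs
#'   `.csv`/`.txt`).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  marker <- numeric(length(session$sc))
  for (on in session$events$onset_s) {
    i0 <- round(on * session$fs) + 1
    marker[i0:min(length(marker), i0 + round(0.05 * session$fs))] <- 5
  }
  resp <- session$resp %||% numeric(length(session$sc))
  if (tolower(tools::file_ext(path)) == "mat") {
    write_mat(list(SC = session$sc, Resp = resp, Marker = marker,
                   fs = session$fs), path)
  } else {
    readr::write_csv(tibble(SC = session$sc, Resp = resp, Marker = marker),
                     path, progress = FALSE)
  }
  invisible(path)
}

#' Construct a noise-free 50 Hz segment with responses at exact positions
#'
#' Boundary-stress helper: places peak-normalized kernels at the given
#' onsets on the scoring grid, with no filtering, so trough samples land
#' exactly where stated (e.g. exactly on a window boundary to exercise the
#' half-open rule).
#'
#' @param onsets_s,amplitudes_uS Equal-length vectors of response onsets
#'   (s, relative to segment start) and amplitudes (uS).
#' @param fs Segment rate, default 50.
#' @param len_s Segment length, default 14.
#' @param rise_s,decay_s Kernel time constants.
#' @return Numeric vector of `len_s * fs` samples.
#' @export
kernel_segment <- function(onsets_s, amplitudes_uS, fs = 50, len_s = 14,
                           rise_s = 0.75, decay_s = 3) {
  stopifnot(length(onsets_s) == length(amplitudes_uS))
  t <- (seq_len(round(len_s * fs)) - 1) / fs
  out <- numeric(length(t))
  for (i in seq_along(onsets_s)) {
    out <- out + scr_kernel(t, onsets_s[i], amplitudes_uS[i], rise_s, decay_s)
  }
  out
}
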