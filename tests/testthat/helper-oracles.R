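# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: the pair search is an exhaustive scan
# over all (trough, peak) index pairs, the ICC oracle goes through
# stats::aov, and filter gains come from the DTFT of the tap sequence.

# Exhaustive trough-to-peak pair search under the scoring rules:
# trough sample i in [start, end) with a valid left flank (an anchor
# >= x[i] + delta appears, walking left, before any sample < x[i]; the
# series start counts); peak sample j > i with t(j) <= end + horizon and a
# valid right flank (a drop to <= x[j] - delta appears, walking right,
# before any sample > x[j]; the series end does not confirm); amplitude
# >= delta; all strictly-interior samples strictly between x[i] and x[j].
# Returns NULL or list(i, j, amp) maximizing amp (ties: earliest i, then j).
oracle_pair_search <- function(values, fs, window, delta, horizon,
                               next_onset = Inf) {
  n <- length(values)
  n_eff <- min(n, floor(next_onset * fs + 1e-9))
  t <- (seq_len(n) - 1) / fs
  best <- NULL
  for (i in seq_len(n_eff)) {
    if (!(t[i] >= window[1] - 1e-9 && t[i] < window[2] - 1e-9)) next
    left_ok <- TRUE
    if (i > 1) {
      left_ok <- NA
      for (k in (i - 1):1) {
        if (values[k] < values[i]) { left_ok <- FALSE; break }
        if (values[k] >= values[i] + delta) { left_ok <- TRUE; break }
      }
      if (is.na(left_ok)) left_ok <- TRUE
    }
    if (!left_ok) next
    for (j in seq_len(n_eff)) {
      if (j <= i) next
      if (t[j] > window[2] + horizon + 1e-9) next
      amp <- values[j] - values[i]
      if (amp < delta) next
      if (j - i > 1) {
        inner <- values[(i + 1):(j - 1)]
        if (any(inner <= values[i]) || any(inner >= values[j])) next
      }
      right_ok <- FALSE
      if (j < n_eff) {
        for (k in (j + 1):n_eff) {
          if (values[k] > values[j]) break
          if (values[k] <= values[j] - delta) { right_ok <- TRUE; break }
        }
      }
      if (!right_ok) next
      if (is.null(best) || amp > best$amp) best <- list(i = i, j = j, amp = amp)
    }
  }
  best
}

# One-way random-effects ICC through stats::aov on long-format data.
oracle_icc_aov <- function(x) {
  x <- as.matrix(x)
  df <- data.frame(y = as.vector(x),
                   target = factor(rep(seq_len(nrow(x)), times = ncol(x))))
  tab <- anova(stats::aov(y ~ target, data = df))
  msb <- tab["target", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(x)
  list(icc = (msb - msw) / (msb + (k - 1) * msw), f = msb / msw)
}

# Filter gain at frequency f from the tap sequence (DTFT magnitude).
dtft_gain <- function(h, f, fs) {
  k <- seq_along(h) - 1
  vapply(f, function(ff) abs(sum(h * exp(-2i * pi * ff * k / fs))),
         numeric(1))
}

# Random 18 s scoring segment at 50 Hz: 0-3 SCR kernels at random onsets
# and amplitudes plus Gaussian noise (sd up to 0.01 uS).  Uses the current
# RNG state; callers set the seed.
random_segment <- function() {
  n_scr <- sample(0:3, 1)
  onsets <- sort(runif(n_scr, 0.5, 11))
  amps <- runif(n_scr, 0.02, 0.6)
  noise_sd <- runif(1, 0, 0.01)
  seg <- kernel_segment(onsets, amps, fs = 50, len_s = 18)
  seg + rnorm(length(seg), 0, noise_sd)
}

# Score one window both ways and check exact agreement.
expect_matches_oracle <- function(seg, window, cfg = interval_config()) {
  got <- score_interval(seg, 50, window, cfg)
  ora <- oracle_pair_search(seg, 50, window, cfg$threshold_uS,
                            cfg$peak_horizon_s)
  if (is.null(ora)) {
    expect_identical(got$status, "zero")
    expect_identical(got$amplitude_uS, 0)
  } else {
    expect_identical(got$status, "auto")
    expect_identical(got$amplitude_uS, ora$amp)
    expect_identical(got$trough_time_s, (ora$i - 1) / 50)
    expect_identical(got$peak_time_s, (ora$j - 1) / 50)
  }
}

# Small fully in-memory session used by I/O and scoring tests: kernels on a
# flat baseline at 1000 Hz.
tiny_session <- function(onsets = c(30, 50, 70), amps = c(0.4, 0.3, 0.5),
                         fir_onset = 2, dur = 100, fs = 1000) {
  t <- (seq_len(dur * fs) - 1) / fs
  sc <- numeric(length(t)) + 5
  for (i in seq_along(onsets)) {
    sc <- sc + scr_kernel(t, onsets[i] + fir_onset, amps[i])
  }
  scr_session(sc = sc, fs = fs, events = onsets)
}
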