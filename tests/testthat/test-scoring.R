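test_that("extrema walker validates peaks and troughs against the threshold", {
  ex <- find_extrema(c(0, 0, 0.05, 0.10, 0.05, 0), 0.02)
  expect_equal(ex$kind, c("trough", "peak", "trough"))
  expect_equal(ex$idx, c(2, 4, 6))
  expect_equal(ex$value, c(0, 0.10, 0))
  expect_equal(ex$confirmed, c(TRUE, TRUE, FALSE))

  expect_equal(nrow(find_extrema(rep(1, 10), 0.02)), 0)     # flat
  expect_equal(nrow(find_extrema(seq(0, 1, 0.1), 0.02)), 0) # monotone
  # total variation below threshold: nothing validates
  expect_equal(nrow(find_extrema(seq(0, 0.015, length.out = 30), 0.02)), 0)
})

test_that("extrema walker output alternates and respects the threshold", {
  set.seed(41)
  for (rep in 1:25) {
    x <- cumsum(rnorm(300, 0, 0.05))
    ex <- find_extrema(x, 0.1)
    if (nrow(ex) < 2) next
    expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))  # alternation
    expect_true(all(diff(ex$idx) > 0))
    confirmed <- ex[ex$confirmed, ]
    if (nrow(confirmed) >= 2) {
      jumps <- abs(diff(confirmed$value))
      expect_true(all(jumps >= 0.1))
    }
  }
})

test_that("a single SCR is scored from its onset trough to its peak", {
  cfg <- interval_config()
  seg <- kernel_segment(2.0, 0.30)
  fir <- score_interval(seg, 50, c(1, 4), cfg, interval = "FIR")
  expect_identical(fir$status, "auto")
  expect_equal(fir$trough_time_s, 2.0)
  expect_equal(fir$amplitude_uS, 0.30, tolerance = 0.01)
  expect_equal(fir$peak_time_s, 2 + scr_kernel_peak_time(), tolerance = 0.05)

  sir <- score_interval(seg, 50, c(4, 7), cfg, interval = "SIR")
  expect_identical(sir$status, "zero")  # no onset in [4, 7)
  expect_identical(sir$amplitude_uS, 0)
})

test_that("the most prominent trough-to-peak pair wins", {
  cfg <- interval_config()
  # two responses onsetting in FIR: a small one then a larger one
  seg <- kernel_segment(c(1.3, 3.5), c(0.10, 0.25))
  fir <- score_interval(seg, 50, c(1, 4), cfg, interval = "FIR")
  expect_identical(fir$status, "auto")
  ora <- oracle_pair_search(seg, 50, c(1, 4), 0.02, 4)
  expect_identical(fir$amplitude_uS, ora$amp)
  # the winning pair reaches the larger response's peak; the small first
  # response's own 0.10 pair is never the answer
  expect_gte(fir$amplitude_uS, 0.25)
  expect_gt(fir$peak_time_s, 4)
})

test_that("flat segments yield zero records in every window", {
  cfg <- interval_config()
  for (w in list(c(1, 4), c(4, 7), c(7, 10))) {
    r <- score_interval(rep(0.3, 900), 50, w, cfg)
    expect_identical(r$status, "zero")
    expect_identical(r$amplitude_uS, 0)
  }
})

test_that("windows outside truncated data become missing_artifact", {
  cfg <- interval_config()
  seg <- kernel_segment(2, 0.3)[1:250]  # 5 s of data
  r <- score_interval(seg, 50, c(7, 10), cfg, interval = "TIR")
  expect_identical(r$status, "missing_artifact")
  expect_true(is.na(r$amplitude_uS))
  r2 <- score_interval(seg, 50, c(1, 4), cfg, interval = "FIR")
  expect_identical(r2$status, "auto")  # FIR window itself is complete
})

test_that("scoring matches the exhaustive pair-search oracle on random segments", {
  set.seed(101)
  cfg <- interval_config()
  for (rep in 1:60) {
    seg <- random_segment()
    win <- list(c(1, 4), c(4, 7), c(7, 10))[[sample(3, 1)]]
    expect_matches_oracle(seg, win, cfg)
  }
})

test_that("raising the threshold never raises amplitudes or revives zeros", {
  set.seed(102)
  for (rep in 1:10) {
    seg <- random_segment()
    amps <- vapply(c(0.01, 0.02, 0.05, 0.1), function(th) {
      score_interval(seg, 50, c(1, 4), interval_config(threshold_uS = th))$amplitude_uS
    }, numeric(1))
    expect_true(all(diff(amps) <= 1e-12))
  }
})

test_that("scored amplitudes are never negative nor below threshold", {
  set.seed(103)
  cfg <- interval_config()
  for (rep in 1:20) {
    seg <- random_segment()
    for (w in list(c(1, 4), c(4, 7), c(7, 10))) {
      r <- score_interval(seg, 50, w, cfg)
      if (r$status == "auto") expect_gte(r$amplitude_uS, cfg$threshold_uS)
      else expect_identical(r$amplitude_uS, 0)
    }
  }
})

test_that("scoring is invariant to a constant baseline shift", {
  set.seed(104)
  cfg <- interval_config()
  seg <- random_segment()
  for (w in list(c(1, 4), c(4, 7))) {
    r0 <- score_interval(seg, 50, w, cfg)
    r1 <- score_interval(seg + 3.7, 50, w, cfg)
    expect_equal(r0$amplitude_uS, r1$amplitude_uS, tolerance = 1e-9)
    expect_identical(r0$status, r1$status)
  }
})

test_that("injected amplitudes are recovered within 5% at the detector level", {
  cfg <- interval_config()
  for (amp in c(0.05, 0.1, 0.2, 0.5, 1.0)) {
    seg <- kernel_segment(2.2, amp)
    r <- score_interval(seg, 50, c(1, 4), cfg, interval = "FIR")
    expect_identical(r$status, "auto")
    expect_lt(abs(r$amplitude_uS - amp) / amp, 0.05)
  }
})

test_that("score_session emits 3 records per event with absolute times", {
  s <- tiny_session()
  recs <- score_session(s, rater = "auto")
  expect_equal(nrow(recs), 9)
  expect_equal(sort(unique(recs$event_index)), 1:3)
  fir <- recs[recs$interval == "FIR" & recs$event_index == 2, ]
  expect_identical(fir$status, "auto")
  expect_equal(fir$trough_time_s, 52, tolerance = 0.15)  # session time
})

test_that("a final event too close to the recording end is missing_artifact", {
  s <- tiny_session(onsets = c(30, 95), dur = 100)
  recs <- score_session(s)
  tir <- recs[recs$event_index == 2 & recs$interval == "TIR", ]
  expect_identical(tir$status, "missing_artifact")
})

test_that("scoring is deterministic: identical runs, byte-identical CSV", {
  s <- tiny_session()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_scores(score_session(s), f1)
  write_scores(score_session(s), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("overrides adjust, null, and validate records", {
  s <- tiny_session()
  recs <- score_session(s)
  fir2 <- recs[recs$event_index == 2 & recs$interval == "FIR", ]

  ov <- tibble::tibble(event_index = 2, interval = "FIR",
                       trough_time_s = fir2$trough_time_s,
                       trough_value_uS = fir2$trough_value_uS,
                       peak_time_s = fir2$peak_time_s + 0.1,
                       peak_value_uS = fir2$peak_value_uS + 0.02)
  out <- apply_overrides(recs, ov)
  new_fir <- out[out$event_index == 2 & out$interval == "FIR", ]
  expect_identical(new_fir$status, "adjusted")
  expect_equal(new_fir$amplitude_uS, fir2$amplitude_uS + 0.02)

  out2 <- apply_overrides(recs, tibble::tibble(
    event_index = 1, interval = "SIR", status = "missing_artifact"))
  expect_identical(
    out2$status[out2$event_index == 1 & out2$interval == "SIR"],
    "missing_artifact")

  expect_error(apply_overrides(recs, tibble::tibble(
    event_index = 99, interval = "FIR", status = "zero")),
    class = "scr_validation_error")
  bad <- ov
  bad$peak_time_s <- bad$trough_time_s - 1
  expect_error(apply_overrides(recs, bad), class = "scr_validation_error")
})

test_that("onsets exactly on a window boundary belong to the later interval", {
  cfg <- interval_config()
  seg <- kernel_segment(4.0, 0.30)  # trough lands exactly at 4.0 s
  fir <- score_interval(seg, 50, c(1, 4), cfg, interval = "FIR")
  sir <- score_interval(seg, 50, c(4, 7), cfg, interval = "SIR")
  expect_identical(fir$status, "zero")
  expect_identical(sir$status, "auto")
  expect_equal(sir$trough_time_s, 4.0)
})

test_that("peaks completing after the window end are still scored", {
  cfg <- interval_config()
  # slow response onsetting late in FIR: peak falls well past 4 s
  seg <- kernel_segment(3.5, 0.30, rise_s = 1.5, decay_s = 6)
  fir <- score_interval(seg, 50, c(1, 4), cfg, interval = "FIR")
  expect_identical(fir$status, "auto")
  expect_gt(fir$peak_time_s, 4)
  expect_equal(fir$trough_time_s, 3.5)
})
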