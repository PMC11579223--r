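test_that("rising-edge extraction finds marker onsets, including one at t = 0", {
  marker <- numeric(60000)
  marker[30001:30050] <- 5
  marker[50001:50050] <- 5
  expect_equal(marker_onsets(marker, 1000), c(30, 50))

  high_at_start <- marker
  high_at_start[1:30] <- 5
  expect_equal(marker_onsets(high_at_start, 1000), c(0, 30, 50))

  expect_length(marker_onsets(numeric(100), 1000), 0)
})

test_that("rising-edge extraction equals a brute-force scan over sample pairs", {
  set.seed(301)
  for (rep in 1:20) {
    m <- as.numeric(runif(500) > 0.8) * runif(1, 1, 10)
    thr <- max(m) / 2
    brute <- which(vapply(seq_along(m), function(i) {
      m[i] >= thr && (i == 1 || m[i - 1] < thr)
    }, logical(1)))
    expect_equal(marker_onsets(m, 100), (brute - 1) / 100)
  }
})

test_that("read_session assembles a validated session from columnar text", {
  tf <- withr::local_tempfile(fileext = ".csv")
  sc <- rep(5, 60000)
  marker <- numeric(60000)
  marker[30001:30050] <- 5
  marker[50001:50050] <- 5
  readr::write_csv(tibble::tibble(SC = sc, Resp = sin(1:60000 / 500),
                                  Marker = marker), tf)
  s <- read_session(tf, c(sc = "SC", events = "Marker", resp = "Resp"),
                    fs = 1000)
  expect_s3_class(s, "scr_session")
  expect_equal(s$events$onset_s, c(30, 50))
  expect_equal(s$events$index, 1:2)
  expect_length(s$resp, 60000)
  expect_equal(session_duration(s), 60)
})

test_that("read_session reports configuration and validation problems", {
  tf <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(A = rep(1, 100), B = rep(0, 100)), tf)
  expect_error(read_session(tf, c(sc = "SC", events = "B"), fs = 100),
               class = "scr_config_error")
  expect_error(read_session(tf, c(events = "B"), fs = 100),
               class = "scr_config_error")
  expect_error(read_session(tf, c(sc = "A", events = "B"), fs = 100),
               class = "scr_validation_error")  # flat marker: no events
  expect_error(read_session(tf, c(sc = "A", events = "B")),
               class = "scr_config_error")      # no fs anywhere
  expect_error(read_session("no/such/file.csv", c(sc = "A"), fs = 10),
               class = "scr_config_error")
})

test_that("a short event variable is taken as onset times in seconds", {
  tf <- withr::local_tempfile(fileext = ".mat")
  write_mat(list(SC = rep(5, 5000), ev = c(1.5, 3.25), fs = 100), tf)
  s <- read_session(tf, c(sc = "SC", events = "ev"))
  expect_equal(s$fs, 100)
  expect_equal(s$events$onset_s, c(1.5, 3.25))
})

test_that("MAT v5 files round-trip named numeric arrays", {
  tf <- withr::local_tempfile(fileext = ".mat")
  vars <- list(x = c(1.5, -2, 3e-8), a_longer_name = matrix(1:6 / 7, 2, 3),
               fs = 1000)
  write_mat(vars, tf)
  back <- read_mat(tf)
  expect_named(back, names(vars))
  expect_equal(back$x, vars$x)
  expect_equal(back$a_longer_name, vars$a_longer_name)
  expect_equal(back$fs, 1000)
})

test_that("annotation CSV has stable schema, empty cells for nulls, LF endings", {
  recs <- dplyr::bind_rows(
    scrscore:::new_score_record(1, "FIR", 31.2, 0.01, 32.4, 0.31, 0.3, "auto", "r1"),
    scrscore:::new_score_record(1, "SIR", status = "zero", rater = "r1"),
    scrscore:::new_score_record(1, "TIR", status = "missing_artifact",
                                amplitude_uS = NA_real_, rater = "r1"),
    scrscore:::new_score_record(2, "FIR", 51, 0, 52, 0.1, 0.1, "auto", "r1"),
    scrscore:::new_score_record(2, "SIR", status = "zero", rater = "r1"),
    scrscore:::new_score_record(2, "TIR", status = "zero", rater = "r1"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_scores(recs, tf)
  raw <- readBin(tf, "raw", file.size(tf))
  expect_false(any(raw == charToRaw("\r")))  # LF only
  lines <- readLines(tf)
  expect_length(lines, 7)  # header + 2 events x 3 intervals
  expect_identical(lines[1], paste(scrscore:::score_cols(), collapse = ","))
  zero_row <- strsplit(lines[3], ",")[[1]]
  expect_identical(zero_row[3:6], rep("", 4))
  expect_identical(zero_row[7], "0.000000")
})

test_that("annotation CSV write -> read is the identity on valid records", {
  set.seed(77)
  truth <- tibble::tibble(
    event_index = rep(1:8, each = 3),
    interval = rep(c("FIR", "SIR", "TIR"), 8),
    amplitude_true_uS = round(runif(24, 0.05, 0.6), 4),
    trough_time_s = seq(2.0015, by = 20, length.out = 24),
    peak_time_s = seq(3.4995, by = 20, length.out = 24))
  recs <- simulate_rater(truth, rater_noise_sd = 0.02, miss_rate = 0.1,
                         seed = 3, rater = "rt")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_scores(recs, tf)
  back <- read_scores(tf)
  expect_equal(as.character(back$interval), as.character(recs$interval))
  expect_equal(back$status, recs$status)
  expect_equal(back$trough_time_s, recs$trough_time_s, tolerance = 5e-4)
  expect_equal(back$peak_time_s, recs$peak_time_s, tolerance = 5e-4)
  expect_equal(back$amplitude_uS, recs$amplitude_uS, tolerance = 1e-5)
})

test_that("invalid annotation tables are rejected with specifics", {
  good <- dplyr::bind_rows(
    scrscore:::new_score_record(1, "FIR", 1, 0, 2, 0.3, 0.3, "auto", "a"),
    scrscore:::new_score_record(1, "SIR", status = "zero", rater = "a"),
    scrscore:::new_score_record(1, "TIR", status = "zero", rater = "a"))

  dup <- dplyr::bind_rows(good, good[1, ])
  expect_error(write_scores(dup, tempfile()), class = "scr_validation_error")

  bad_order <- good
  bad_order$trough_time_s[1] <- 5  # trough after peak on an auto record
  expect_error(validate_scores(bad_order), class = "scr_validation_error")

  tf <- withr::local_tempfile(fileext = ".csv")
  write_scores(good, tf)
  lines <- readLines(tf)
  lines[2] <- sub("FIR", "EIR", lines[2])
  writeLines(lines, tf)
  expect_error(read_scores(tf), class = "scr_parse_error")

  lines <- readLines(tf)
  lines[2] <- sub("EIR", "FIR", lines[2])
  lines[3] <- sub("zero", "perhaps", lines[3])
  writeLines(lines, tf)
  expect_error(read_scores(tf), class = "scr_parse_error")
})
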