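test_that("identical raters give ICC = 1", {
  x <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- icc_oneway(x)
  expect_equal(r$icc, 1)
  expect_equal(r$msw, 0)
})

test_that("a constant rater offset lowers the agreement ICC below 1", {
  a <- c(1, 2, 3, 4)
  x <- cbind(a, a + 1)
  r <- icc_oneway(x)
  ora <- oracle_icc_aov(x)
  expect_equal(r$icc, ora$icc, tolerance = 1e-12)
  expect_equal(r$f_stat, ora$f, tolerance = 1e-12)
  expect_lt(r$icc, 1)
})

test_that("negative ICC arises when within-target variance dominates", {
  x <- rbind(c(1, 5), c(5, 1), c(2, 4), c(4, 2))
  r <- icc_oneway(x)
  expect_lt(r$icc, 0)
  expect_equal(r$icc, oracle_icc_aov(x)$icc, tolerance = 1e-12)
})

test_that("icc_oneway equals the ANOVA oracle on random matrices", {
  set.seed(201)
  for (rep in 1:40) {
    n <- sample(3:25, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, mean = runif(1, -2, 2)), n, k)
    r <- icc_oneway(x)
    ora <- oracle_icc_aov(x)
    expect_equal(r$icc, ora$icc, tolerance = 1e-10)
    expect_equal(r$f_stat, ora$f, tolerance = 1e-10)
  }
})

test_that("ICC is invariant to a global constant but not a per-rater one", {
  set.seed(202)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(icc_oneway(x)$icc, icc_oneway(x + 5)$icc, tolerance = 1e-12)
  shifted <- x
  shifted[, 2] <- shifted[, 2] + 2
  expect_lt(icc_oneway(shifted)$icc, icc_oneway(x)$icc)
})

test_that("icc_oneway guards its preconditions", {
  expect_error(icc_oneway(cbind(1:5)), class = "scr_validation_error")
  expect_error(icc_oneway(cbind(1:2, 2:3)), class = "scr_validation_error")
  expect_warning(r <- icc_oneway(matrix(2, 5, 2)))
  expect_equal(r$icc, 1)
  expect_message(r2 <- icc_oneway(cbind(c(1, 2, 3, NA), c(1, 2, 3, 4))),
                 "Dropping")
  expect_equal(r2$n_targets, 3)
})

test_that("average_scores averages non-missing trials, zeros included", {
  recs <- dplyr::bind_rows(
    scrscore:::new_score_record(1, "FIR", 1, 0, 2, 0.2, 0.2, "auto", "a"),
    scrscore:::new_score_record(2, "FIR", status = "zero", rater = "a"),
    scrscore:::new_score_record(3, "FIR", 1, 0, 2, 0.1, 0.1, "auto", "a"),
    scrscore:::new_score_record(4, "FIR", 1, 0, 2, 0.1, 0.1, "auto", "a"))
  recs$participant <- "p1"
  out <- average_scores(recs)
  expect_equal(out$mean_amplitude_uS, 0.1)
  expect_equal(out$n_trials, 4)

  # order invariance
  out2 <- average_scores(recs[sample(4), ])
  expect_equal(out2, out)

  # all-missing participant dropped with a warning
  miss <- recs
  miss$status <- "missing_artifact"
  miss$amplitude_uS <- NA_real_
  miss[c("trough_time_s", "trough_value_uS", "peak_time_s",
         "peak_value_uS")] <- NA_real_
  miss$participant <- "p2"
  expect_warning(out3 <- average_scores(dplyr::bind_rows(recs, miss)))
  expect_false("p2" %in% out3$participant)
})

test_that("Bland-Altman summaries match hand arithmetic", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$limits, c(0, 0))
  expect_equal(nrow(ba0$outliers), 0)

  # d = (1, -1, 1, -1): mean 0, sample SD sqrt(4/3), limits +/- 1.96 SD
  ba <- bland_altman(c(2, 1, 2, 1), c(1, 2, 1, 2))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1.1547, tolerance = 1e-4)
  expect_equal(ba$limits, c(-2.2632, 2.2632), tolerance = 1e-4)

  expect_error(bland_altman(1:2, 2:3), class = "scr_validation_error")
  expect_error(bland_altman(1:3, 1:4), class = "scr_validation_error")
})

test_that("Bland-Altman limits cover ~95% of Gaussian differences", {
  set.seed(203)
  truth <- rnorm(1000, 0.3, 0.15)
  a <- truth + rnorm(1000, 0, 0.05)
  b <- truth + rnorm(1000, 0, 0.05)
  ba <- bland_altman(a, b)
  inside <- 1 - nrow(ba$outliers) / ba$n
  expect_gte(inside, 0.93)
  expect_lte(inside, 0.97)
})

test_that("agreement_report pairs records and exposes tidy summaries", {
  set.seed(204)
  truth <- tibble::tibble(
    event_index = rep(1:40, each = 3),
    interval = rep(c("FIR", "SIR", "TIR"), 40),
    amplitude_true_uS = stats::rlnorm(120, log(0.15), 0.5),
    trough_time_s = seq(2, by = 20, length.out = 120),
    peak_time_s = seq(3, by = 20, length.out = 120))
  a <- simulate_rater(truth, 0.02, 0.05, seed = 1, rater = "A")
  b <- simulate_rater(truth, 0.02, 0.05, seed = 2, rater = "B")
  rep_tt <- agreement_report(a, b)
  expect_s3_class(rep_tt, "scr_agreement")
  expect_lt(rep_tt$n_targets, 120)   # missing/artifact dropped pairwise
  expect_gt(rep_tt$icc$icc, 0.5)
  g <- glance(rep_tt)
  expect_identical(g$mode, "trial_by_trial")
  expect_true(all(c("icc", "mean_diff", "n_outliers") %in% names(g)))
  expect_s3_class(autoplot(rep_tt$ba), "ggplot")
})

test_that("Pareto tables sort by count with alphabetical ties and sum to 100%", {
  p <- pareto_table(c(rep("latency interval", 5), rep("bad SCR data", 3),
                      rep("peak shoulder", 2)))
  expect_equal(p$count, c(5, 3, 2))
  expect_equal(p$cumulative_pct, c(50, 80, 100))

  single <- pareto_table(rep("only", 4))
  expect_equal(single$cumulative_pct, 100)

  tie <- pareto_table(c("b", "a", "b", "a", "c"))
  expect_equal(tie$category, c("a", "b", "c"))

  set.seed(205)
  labs <- sample(letters[1:5], 137, replace = TRUE)
  expect_equal(sum(pareto_table(labs)$count), 137)
  expect_error(pareto_table(character(0)), class = "scr_validation_error")
  expect_s3_class(autoplot(pareto_table(labs)), "ggplot")
})
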