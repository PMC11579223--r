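#' One-way random-effects agreement ICC
#'
#' Intraclass correlation from the one-way ANOVA decomposition of an
#' n targets x k raters score matrix:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`, with `F = MSB / MSW` on
#' `(n - 1, n (k - 1))` degrees of freedom.  This "agreement" form treats
#' rater identity as part of the error, so systematic rater offsets lower
#' the ICC.  Rows containing missing values (artifact trials) are dropped
#' pairwise-complete with a message; non-responses enter as 0.
#'
#' @param x Numeric matrix or data frame, targets in rows, raters in
#'   columns (k >= 2, at least 3 complete rows).
#' @return An object of class `scr_icc`: list with `icc`, `f_stat`, `df1`,
#'   `df2`, `p_value`, `n_targets`, `k_raters`, `msb`, `msw`.
#' @export
#' @examples
#' icc_oneway(cbind(a = c(1, 2, 3, 4), b = c(1.1, 2.0, 2.9, 4.2)))
icc_oneway <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) {
    abort("Need at least two raters (columns).", class = "scr_validation_error")
  }
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    message(sprintf("Dropping %d target(s) with missing scores.", sum(!complete)))
    x <- x[complete, , drop = FALSE]
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 3) {
    abort("Need at least three complete targets (rows).",
          class = "scr_validation_error")
  }
  row_means <- rowMeans(x)
  grand <- mean(x)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((x - row_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msw == 0 && msb == 0) {
    warn("All scores identical; ICC defined as 1.")
    icc <- 1; f <- NaN
  } else if (msw == 0) {
    icc <- 1; f <- Inf
  } else {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    f <- msb / msw
  }
  structure(list(icc = icc, f_stat = f, df1 = n - 1, df2 = n * (k - 1),
                 p_value = pf(f, n - 1, n * (k - 1), lower.tail = FALSE),
                 n_targets = n, k_raters = k, msb = msb, msw = msw),
            class = "scr_icc")
}

#' @export
print.scr_icc <- function(x, ...) {
  cat(sprintf("One-way random-effects agreement ICC: %.4f\n", x$icc))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g  (n = %d targets, k = %d raters)\n",
              x$df1, x$df2, x$f_stat, x$p_value, x$n_targets, x$k_raters))
  invisible(x)
}

#' @method tidy scr_icc
#' @export
tidy.scr_icc <- function(x, ...) {
  tibble(term = "icc", estimate = x$icc, statistic = x$f_stat,
         df1 = x$df1, df2 = x$df2, p.value = x$p_value)
}

#' @method glance scr_icc
#' @export
glance.scr_icc <- function(x, ...) {
  tibble(icc = x$icc, f_stat = x$f_stat, p.value = x$p_value,
         n_targets = x$n_targets, k_raters = x$k_raters)
}

#' Per-participant mean amplitudes
#'
#' Averages score amplitudes over trials within the supplied grouping
#' (participant x interval by default, optionally also phase or condition
#' columns present in the records).  Non-responses count as 0;
#' missing/artifact trials are excluded from the mean; a participant whose
#' trials are all missing is dropped with a warning.
#'
#' @param records Score records carrying a `participant` column (bind rows
#'   over sessions and add it, or pass `participants`).
#' @param participants Optional vector of participant ids, recycled along
#'   rows of `records`, used when the records carry no `participant`
#'   column.
#' @param by Grouping columns. Default `c("participant", "interval")`.
#' @return Tibble with the grouping columns, `mean_amplitude_uS` and
#'   `n_trials` (non-missing trials averaged).
#' @export
average_scores <- function(records, participants = NULL,
                           by = c("participant", "interval")) {
  records <- as_tibble(records)
  if (!is.null(participants)) records$participant <- participants
  missing_cols <- setdiff(by, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("Records lack grouping column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "scr_validation_error")
  }
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_amplitude_uS = mean(.data$amplitude_uS[.data$status != "missing_artifact"]),
      n_trials = sum(.data$status != "missing_artifact"),
      .groups = "drop")
  dropped <- out$n_trials == 0
  if (any(dropped)) {
    warn(sprintf("%d group(s) had only missing/artifact trials; dropped.",
                 sum(dropped)))
    out <- out[!dropped, ]
  }
  out
}

#' Bland-Altman agreement analysis
#'
#' Paired differences `d = a - b` against paired means `(a + b) / 2`, with
#' limits of agreement `mean(d) +/- 1.96 sd(d)` (sample SD, n - 1).  Pairs
#' outside the limits are flagged as outliers for qualitative (Pareto)
#' follow-up.  The confidence interval of the mean difference is also
#' reported but is not used for outlier flagging.
#'
#' @param a,b Equal-length numeric score vectors (n >= 3).  Pairs with a
#'   missing member are dropped.
#' @return Object of class `scr_blandaltman`: list with `mean_diff`,
#'   `sd_diff`, `limits` (length 2), `ci_mean` (95% CI of the mean
#'   difference), `n`, and `data` / `outliers` tibbles (`id`, `mean`,
#'   `diff`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) {
    abort("`a` and `b` must have equal length.", class = "scr_validation_error")
  }
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) {
    abort("Need at least three complete pairs.", class = "scr_validation_error")
  }
  d <- a - b
  m <- (a + b) / 2
  md <- mean(d); sdd <- sd(d)
  limits <- c(md - 1.96 * sdd, md + 1.96 * sdd)
  dat <- tibble(id = which(keep), mean = m, diff = d)
  out <- dat[d < limits[1] | d > limits[2], ]
  structure(list(mean_diff = md, sd_diff = sdd, limits = limits,
                 ci_mean = md + c(-1.96, 1.96) * sdd / sqrt(n),
                 n = n, data = dat, outliers = out),
            class = "scr_blandaltman")
}

#' @export
print.scr_blandaltman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4f uS, SD %.4f, limits [%.4f, %.4f]\n",
              x$mean_diff, x$sd_diff, x$limits[1], x$limits[2]))
  cat(sprintf("  n = %d pairs, %d outside the limits\n", x$n, nrow(x$outliers)))
  invisible(x)
}

#' @method tidy scr_blandaltman
#' @export
tidy.scr_blandaltman <- function(x, ...) x$data

#' @method glance scr_blandaltman
#' @export
glance.scr_blandaltman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
         lower_limit = x$limits[1], upper_limit = x$limits[2],
         n = x$n, n_outliers = nrow(x$outliers))
}

#' @method autoplot scr_blandaltman
#' @export
autoplot.scr_blandaltman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = object$limits, linewidth = 0.8) +
    ggplot2::labs(x = "mean of paired scores (uS)",
                  y = "difference (uS)")
}

#' Combined agreement report for two score sets
#'
#' Pairs two score tables on (event_index, interval) -- or on participant
#' means when `mode = "average_scores"` and the records carry a
#' `participant` column -- then computes the one-way agreement ICC and the
#' Bland-Altman summary.  Pairs where either rater marked the trial
#' missing/artifact are excluded; non-responses enter as 0.
#'
#' @param a,b Score tables from two raters.
#' @param mode `"trial_by_trial"` (default) or `"average_scores"`.
#' @return Object of class `scr_agreement`: list with `icc` (an `scr_icc`),
#'   `ba` (an `scr_blandaltman`), `mode`, `n_targets`.
#' @export
agreement_report <- function(a, b, mode = c("trial_by_trial", "average_scores")) {
  mode <- match.arg(mode)
  if (mode == "average_scores") {
    ma <- average_scores(a); mb <- average_scores(b)
    paired <- dplyr::inner_join(ma, mb, by = setdiff(names(ma),
                                                     c("mean_amplitude_uS", "n_trials")),
                                suffix = c("_a", "_b"))
    xa <- paired$mean_amplitude_uS_a; xb <- paired$mean_amplitude_uS_b
  } else {
    pa <- dplyr::select(as_tibble(a), "event_index", "interval", "amplitude_uS")
    pb <- dplyr::select(as_tibble(b), "event_index", "interval", "amplitude_uS")
    paired <- dplyr::inner_join(pa, pb, by = c("event_index", "interval"),
                                suffix = c("_a", "_b"))
    xa <- paired$amplitude_uS_a; xb <- paired$amplitude_uS_b
  }
  keep <- is.finite(xa) & is.finite(xb)
  icc <- icc_oneway(cbind(a = xa[keep], b = xb[keep]))
  ba <- bland_altman(xa[keep], xb[keep])
  structure(list(icc = icc, ba = ba, mode = mode, n_targets = sum(keep)),
            class = "scr_agreement")
}

#' @export
print.scr_agreement <- function(x, ...) {
  cat(sprintf("Agreement report (%s, n = %d targets)\n", x$mode, x$n_targets))
  print(x$icc); print(x$ba)
  invisible(x)
}

#' @method glance scr_agreement
#' @export
glance.scr_agreement <- function(x, ...) {
  dplyr::bind_cols(tibble(mode = x$mode), glance(x$icc)[1:3],
                   glance(x$ba)[c("mean_diff", "sd_diff", "lower_limit",
                                  "upper_limit", "n_outliers")])
}

#' Pareto table of discrepancy causes
#'
#' Tabulates qualitative discrepancy labels (assigned by a human reviewer
#' to each outlying score pair), sorted by descending count with ties
#' broken alphabetically, plus cumulative percentages.
#'
#' @param labels Character vector of category labels, one per discrepancy.
#' @return Tibble of class `scr_pareto` with `category`, `count`,
#'   `cumulative_pct`.
#' @export
#' @examples
#' pareto_table(c(rep("latency interval", 5), rep("bad SCR data", 3),
#'                rep("peak shoulder", 2)))
pareto_table <- function(labels) {
  if (length(labels) == 0) {
    abort("No discrepancy labels supplied.", class = "scr_validation_error")
  }
  out <- tibble(category = as.character(labels)) |>
    dplyr::count(.data$category, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$category) |>
    dplyr::mutate(cumulative_pct = 100 * cumsum(.data$count) / sum(.data$count))
  class(out) <- c("scr_pareto", class(out))
  out
}

#' @method autoplot scr_pareto
#' @export
autoplot.scr_pareto <- function(object, ...) {
  df <- as_tibble(object)
  df$category <- factor(df$category, levels = df$category)
  scale <- max(df$count) / 100
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative_pct * scale, group = 1)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative_pct * scale)) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "cumulative %")) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
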