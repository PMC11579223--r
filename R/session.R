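#' Build a recording session
#'
#' A session holds the skin-conductance trace (in microsiemens), an optional
#' respiration trace, the sampling rate, and the event markers (CS onsets)
#' around which trials are scored.
#'
#' @param sc Numeric vector, skin conductance in uS.
#' @param fs Sampling rate in Hz (> 0).
#' @param events Data frame with columns `index` (1-based trial number,
#'   consecutive), `onset_s` (seconds from recording start, strictly
#'   increasing, within the recording) and optionally `label` (condition
#'   string such as "CS+" / "CS-", default empty). A bare numeric vector of
#'   onset times is also accepted.
#' @param resp Optional numeric vector, respiration (arbitrary units); must
#'   have the same length as `sc`.
#' @param meta Named list of free-form provenance (source file, channel
#'   names, ...).
#'
#' @return An object of class `scr_session`.
#' @export
#' @examples
#' s <- scr_session(sc = sin(seq(0, 20, by = 0.001)), fs = 1000,
#'                  events = c(5, 12))
#' s
scr_session <- function(sc, fs, events, resp = NULL, meta = list()) {
  if (!is.numeric(sc) || length(sc) == 0) {
    abort("`sc` must be a non-empty numeric vector.", class = "scr_validation_error")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "scr_validation_error")
  }
  events <- as_event_table(events)
  x <- structure(
    list(sc = as.numeric(sc), resp = if (!is.null(resp)) as.numeric(resp),
         events = events, fs = as.numeric(fs), meta = meta),
    class = "scr_session"
  )
  validate_scr_session(x)
}

as_event_table <- function(events) {
  if (is.numeric(events) && is.null(dim(events))) {
    events <- tibble(index = seq_along(events), onset_s = as.numeric(events),
                     label = "")
  }
  events <- as_tibble(events)
  if (!all(c("index", "onset_s") %in% names(events))) {
    abort("`events` needs columns `index` and `onset_s`.",
          class = "scr_validation_error")
  }
  if (!"label" %in% names(events)) events$label <- ""
  events$label[is.na(events$label)] <- ""
  events[c("index", "onset_s", "label")]
}

validate_scr_session <- function(x) {
  ev <- x$events
  dur <- length(x$sc) / x$fs
  if (!is.null(x$resp) && length(x$resp) != length(x$sc)) {
    abort("All channel series must have equal length.", class = "scr_validation_error")
  }
  if (nrow(ev) > 0) {
    if (!identical(as.integer(ev$index), seq_len(nrow(ev)))) {
      abort("Event indices must be unique and consecutive from 1.",
            class = "scr_validation_error")
    }
    if (any(ev$onset_s < 0) || any(ev$onset_s >= dur)) {
      abort(sprintf("Event onsets must lie within [0, %.3f s).", dur),
            class = "scr_validation_error")
    }
    if (nrow(ev) > 1 && any(diff(ev$onset_s) <= 0)) {
      abort("Event onsets must be strictly increasing.",
            class = "scr_validation_error")
    }
  }
  x
}

#' @export
print.scr_session <- function(x, ...) {
  dur <- length(x$sc) / x$fs
  cat(sprintf("<scr_session> %.1f s at %g Hz (%d samples)\n",
              dur, x$fs, length(x$sc)))
  cat(sprintf("  channels: sc%s\n", if (is.null(x$resp)) "" else ", resp"))
  cat(sprintf("  events:   %d", nrow(x$events)))
  if (nrow(x$events) > 0) {
    cat(sprintf(" (first at %.2f s, last at %.2f s)",
                min(x$events$onset_s), max(x$events$onset_s)))
  }
  cat("\n")
  if (length(x$meta)) {
    cat("  meta:     ", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Session duration in seconds
#' @param session An `scr_session`.
#' @return Length of the recording in seconds.
#' @export
session_duration <- function(session) length(session$sc) / session$fs

#' Plot a recording session
#'
#' Stacked panels for skin conductance, respiration (if present) and event
#' markers, mirroring the usual acquisition-software view.
#'
#' @param object An `scr_session`.
#' @param downsample_to Plotting rate in Hz; the trace is thinned to roughly
#'   this rate before plotting so long sessions stay responsive.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scr_session
#' @export
autoplot.scr_session <- function(object, downsample_to = 25, ...) {
  step <- max(1L, floor(object$fs / downsample_to))
  idx <- seq(1L, length(object$sc), by = step)
  df <- tibble(time_s = (idx - 1) / object$fs,
               value = object$sc[idx], channel = "skin conductance (uS)")
  if (!is.null(object$resp)) {
    df <- dplyr::bind_rows(df, tibble(time_s = (idx - 1) / object$fs,
                                      value = object$resp[idx],
                                      channel = "respiration"))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_vline(data = object$events,
                                 ggplot2::aes(xintercept = .data$onset_s),
                                 colour = "red", linetype = "dotted",
                                 linewidth = 0.3)
  }
  p
}
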