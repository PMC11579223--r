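#' Plot one scored trial
#'
#' The preprocessed 50 Hz segment for a single event with the three latency
#' windows shaded and the scored trough/peak markers overlaid -- the static
#' counterpart of an interactive scoring view, useful when deciding whether
#' to override a record.
#'
#' @param session An [scr_session()].
#' @param records Score records for the session (from [score_session()]).
#' @param event_index Which trial to plot.
#' @param preproc,cfg The configurations used for scoring.
#' @return A ggplot object.
#' @export
plot_trial <- function(session, records, event_index,
                       preproc = preproc_config(), cfg = interval_config()) {
  segs <- preprocess_session(session, preproc)
  seg <- segs[segs$event_index == event_index, ]
  if (nrow(seg) == 0) {
    abort(sprintf("No event %d in session.", event_index),
          class = "scr_validation_error")
  }
  vals <- seg$values[[1]]
  df <- tibble(time_s = seg$t0_s + (seq_along(vals) - 1) / seg$fs,
               sc = vals)
  win <- dplyr::mutate(cfg$windows, start_abs = .data$start_s + seg$t0_s,
                       end_abs = .data$end_s + seg$t0_s)
  rec <- dplyr::filter(as_tibble(records),
                       .data$event_index == !!event_index,
                       .data$status %in% c("auto", "adjusted"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$sc)) +
    ggplot2::geom_rect(data = win, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$start_abs, xmax = .data$end_abs,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$interval), alpha = 0.15) +
    ggplot2::geom_vline(xintercept = c(seg$t0_s, seg$t0_s + cfg$cs_duration_s),
                        linewidth = 0.4) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "skin conductance (uS, high-passed)",
                  fill = "window",
                  title = sprintf("Event %d", event_index))
  if (nrow(rec) > 0) {
    pts <- dplyr::bind_rows(
      tibble(time_s = rec$trough_time_s, sc = rec$trough_value_uS, what = "trough"),
      tibble(time_s = rec$peak_time_s, sc = rec$peak_value_uS, what = "peak"))
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(shape = .data$what),
                                 colour = "red", size = 2.5)
  }
  p
}
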