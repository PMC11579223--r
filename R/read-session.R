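#' Read a physiological recording into a session
#'
#' Loads a multi-channel recording from a classic MAT-file (v5 dialect) or a
#' plain columnar text file (CSV/TSV with a header row, one column per
#' channel) and assembles a validated [scr_session()].  The event channel
#' may be either a continuous marker trace sampled like the skin-conductance
#' channel (events are extracted at rising edges) or a short vector of onset
#' times in seconds.
#'
#' @param path Path to a `.mat`, `.csv`, `.tsv` or `.txt` file.
#' @param channel_map Named character vector mapping roles to channel
#'   (variable/column) names.  Role `sc` is required; `events` names the
#'   marker channel or onset vector; `resp` is optional.  Example:
#'   `c(sc = "SkinCond", events = "Event", resp = "Resp")`.
#' @param fs Sampling rate in Hz.  Taken from the file when it contains a
#'   scalar variable/column named `fs` (MAT) and otherwise required.
#' @param marker_threshold Threshold for rising-edge detection on a
#'   continuous marker channel; default half the channel maximum.
#' @return An [scr_session()].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' sc <- rep(5, 2000); ev <- rep(0, 2000); ev[501:520] <- 1
#' readr::write_csv(tibble::tibble(SC = sc, Marker = ev), tf)
#' read_session(tf, c(sc = "SC", events = "Marker"), fs = 100)
read_session <- function(path, channel_map, fs = NULL,
                         marker_threshold = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "scr_config_error")
  }
  if (!"sc" %in% names(channel_map)) {
    abort("`channel_map` must name a skin-conductance channel under role `sc`.",
          class = "scr_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  vars <- if (ext == "mat") {
    read_mat(path)
  } else {
    df <- readr::read_delim(path, delim = if (ext == "tsv") "\t" else ",",
                            show_col_types = FALSE, progress = FALSE)
    as.list(df)
  }
  for (role in names(channel_map)) {
    nm <- channel_map[[role]]
    if (!nm %in% names(vars)) {
      abort(sprintf("Channel '%s' (role `%s`) not found in %s. Available: %s",
                    nm, role, basename(path),
                    paste(names(vars), collapse = ", ")),
            class = "scr_config_error")
    }
  }
  if (is.null(fs) && "fs" %in% names(vars) && length(vars$fs) == 1) {
    fs <- as.numeric(vars$fs)
  }
  if (is.null(fs)) {
    abort("Sampling rate not found in file; supply `fs`.",
          class = "scr_config_error")
  }
  if (!is.numeric(fs) || fs <= 0) {
    abort("`fs` must be positive.", class = "scr_validation_error")
  }
  sc <- as.numeric(vars[[channel_map[["sc"]]]])
  resp <- if ("resp" %in% names(channel_map)) {
    as.numeric(vars[[channel_map[["resp"]]]])
  }
  events <- tibble(index = integer(), onset_s = numeric(), label = character())
  if ("events" %in% names(channel_map)) {
    ev_raw <- as.numeric(vars[[channel_map[["events"]]]])
    if (length(ev_raw) == length(sc)) {
      onsets <- marker_onsets(ev_raw, fs, threshold = marker_threshold)
    } else {
      onsets <- sort(ev_raw)  # already onset times in seconds
    }
    if (length(onsets) == 0) {
      abort(sprintf(
        paste0("No events found in channel '%s' ",
               "(n = %d, min = %g, max = %g, threshold = %g)."),
        channel_map[["events"]], length(ev_raw), min(ev_raw), max(ev_raw),
        marker_threshold %||% (max(ev_raw) / 2)),
        class = "scr_validation_error")
    }
    events <- tibble(index = seq_along(onsets), onset_s = onsets, label = "")
  }
  scr_session(sc = sc, fs = fs, events = events, resp = resp,
              meta = list(source = path,
                          channel_map = as.list(channel_map)))
}

#' Extract event onsets from a continuous marker channel
#'
#' An event begins wherever the marker transitions from below the threshold
#' to at/above it.  A channel that is already high at the first sample emits
#' an event at t = 0 (the edge at the start counts; drop it afterwards if it
#' is an acquisition artifact).
#'
#' @param marker Numeric marker trace.
#' @param fs Sampling rate (Hz).
#' @param threshold Level defining "high"; default `max(marker) / 2`.
#' @return Numeric vector of onset times in seconds.
#' @export
marker_onsets <- function(marker, fs, threshold = NULL) {
  if (max(marker) == min(marker)) return(numeric(0))  # flat channel: no edges
  threshold <- threshold %||% (max(marker) / 2)
  high <- marker >= threshold
  rising <- which(high & !dplyr::lag(high, default = FALSE))
  (rising - 1) / fs
}
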