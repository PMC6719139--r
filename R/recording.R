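#' Construct a raw multi-axis sensor recording
#'
#' A `raw_recording` holds irregularly sampled, time-stamped sensor channels
#' on a common clock: up to three accelerometer axes in g (aX longitudinal,
#' down; aY frontal, right; aZ dorsoventral, out), three gyroscope axes in
#' deg/s (right-hand rule), and an optional single-lead ECG in mV.
#' Timestamps are absolute seconds, zero-based at acquisition start, and must
#' be strictly increasing; all downstream beat timestamps share this clock.
#'
#' @param timestamps numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param channels named list of numeric vectors, each the same length as
#'   `timestamps`. Conventional names: `aX`, `aY`, `aZ`, `gX`, `gY`, `gZ`,
#'   `ecg`.
#' @param meta list of metadata; recognised entries are `subject`,
#'   `condition` ("rest" or "recovery") and `nominal_fs` (Hz, default 250).
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(timestamps, channels = list(), meta = list()) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) < 2) stop("insufficient data: need at least 2 samples")
  if (any(diff(timestamps) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(meta$nominal_fs)) meta$nominal_fs <- 250
  if (meta$nominal_fs <= 0) stop("nominal_fs must be > 0")
  channels <- lapply(channels, as.numeric)
  lens <- vapply(channels, length, integer(1))
  if (length(lens) && any(lens != length(timestamps)))
    stop("all channels must match the timestamp length")
  structure(list(timestamps = timestamps, channels = channels, meta = meta),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples, %.2f s, channels: %s\n",
              length(x$timestamps), duration(x),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `raw_recording`.
#' @return last timestamp minus first, seconds.
#' @export
duration <- function(rec) {
  diff(range(rec$timestamps))
}

#' Column-mapping dialect for recording CSV files
#'
#' Describes which CSV columns hold the timestamp and each signal channel,
#' so that arbitrarily named files can be ingested. Comma separated, header
#' required, '.' decimal mark, UTF-8.
#'
#' @param time name of the timestamp column (seconds).
#' @param channels named character vector mapping channel ids to column
#'   names, e.g. `c(aZ = "az_g", gX = "gx_dps", ecg = "ecg_mv")`.
#' @return a list of class `recording_dialect`.
#' @export
recording_dialect <- function(time = "t",
                              channels = c(aX = "aX", aY = "aY", aZ = "aZ",
                                           gX = "gX", gY = "gY", gZ = "gZ",
                                           ecg = "ecg")) {
  structure(list(time = time, channels = channels),
            class = "recording_dialect")
}

#' Read a recording from CSV
#'
#' Rows whose timestamp does not strictly increase (duplicates or
#' serial-acquisition reorderings) are dropped with a warning, matching how
#' temporal inconsistencies in streamed sensor data are cleaned before
#' analysis. Dialect channels absent from the file are silently skipped;
#' at least one must be present.
#'
#' @param path CSV file path.
#' @param dialect a [recording_dialect()].
#' @param meta metadata list passed to [raw_recording()].
#' @return a `raw_recording`.
#' @export
read_recording <- function(path, dialect = recording_dialect(), meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!dialect$time %in% names(df))
    stop("format error: no timestamp column '", dialect$time, "' in ", path)
  present <- dialect$channels[dialect$channels %in% names(df)]
  if (!length(present))
    stop("format error: none of the dialect channels found in ", path)
  t <- as.numeric(df[[dialect$time]])
  ## a row is kept iff its timestamp exceeds every earlier kept timestamp
  keep <- logical(length(t))
  last <- -Inf
  for (i in seq_along(t)) {
    if (!is.na(t[i]) && t[i] > last) {
      keep[i] <- TRUE
      last <- t[i]
    }
  }
  if (any(!keep))
    warning(sum(!keep), " non-monotone or duplicate timestamp row(s) dropped")
  if (sum(keep) < 2) stop("insufficient data: fewer than 2 usable samples")
  chans <- lapply(present, function(col) as.numeric(df[[col]])[keep])
  names(chans) <- names(present)
  raw_recording(t[keep], chans, meta)
}

#' Write a recording to CSV
#'
#' Header row names the timestamp column and channels; timestamps are
#' serialised with 9 decimal places so read/write round-trips are lossless
#' at well below sample spacing.
#'
#' @param rec a `raw_recording`.
#' @param path output CSV path.
#' @param dialect a [recording_dialect()] giving the column names to emit.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = recording_dialect()) {
  df <- data.frame(t = sprintf("%.9f", rec$timestamps),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- dialect$time
  for (ch in names(rec$channels)) {
    col <- if (ch %in% names(dialect$channels)) dialect$channels[[ch]] else ch
    df[[col]] <- sprintf("%.10g", rec$channels[[ch]])
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write recording to ", path)
  invisible(path)
}

#' Slice a recording onto a rolling analysis buffer
#'
#' A `buffer_segment` holds the samples with timestamp in
#' `(window_end - buffer_span, window_end]` — the "most recent
#' `buffer_span` seconds" at refresh instant `window_end`.
#'
#' @param rec a `raw_recording`.
#' @param window_end absolute end time of the buffer, seconds.
#' @param buffer_span buffer length, seconds (default 10).
#' @param step refresh period, seconds (default 1).
#' @return a list of class `buffer_segment` with elements `recording`,
#'   `window_end`, `buffer_span`, `step`.
#' @export
buffer_segment <- function(rec, window_end, buffer_span = 10, step = 1) {
  idx <- which(rec$timestamps > window_end - buffer_span &
               rec$timestamps <= window_end)
  if (length(idx) < 2)
    stop("insufficient data in buffer ending at ", window_end)
  sub <- raw_recording(rec$timestamps[idx],
                       lapply(rec$channels, function(v) v[idx]),
                       rec$meta)
  structure(list(recording = sub, window_end = window_end,
                 buffer_span = buffer_span, step = step),
            class = "buffer_segment")
}

#' Emulate real-time buffering of a recording
#'
#' Replays a full recording as the ordered sequence of rolling buffers a live
#' system would have seen: the first buffer ends one full `buffer_span` after
#' the first sample (no warm-up emissions before a whole buffer has accrued)
#' and successive buffers advance by `step`. Acquisition gaps longer than
#' `gap_warn` seconds trigger a warning but processing continues.
#'
#' @param rec a `raw_recording` of duration at least 2 s.
#' @param buffer_span buffer length, seconds.
#' @param step refresh period, seconds.
#' @param gap_warn gap length that triggers a dropout warning, seconds.
#' @return list of [buffer_segment()]s (possibly empty when the recording is
#'   shorter than `buffer_span`).
#' @export
stream_buffers <- function(rec, buffer_span = 10, step = 1, gap_warn = 1) {
  stopifnot(buffer_span > 0, step > 0)
  if (duration(rec) < 2)
    stop("insufficient data: recording shorter than 2 s")
  gaps <- diff(rec$timestamps)
  if (any(gaps > gap_warn))
    warning(sum(gaps > gap_warn), " acquisition gap(s) longer than ",
            gap_warn, " s")
  t0 <- rec$timestamps[1]
  tn <- rec$timestamps[length(rec$timestamps)]
  if (tn - t0 < buffer_span) return(list())
  ends <- seq(t0 + buffer_span, tn, by = step)
  lapply(ends, function(e) buffer_segment(rec, e, buffer_span, step))
}
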