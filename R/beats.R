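#' Construct an ordered beat list
#'
#' @param timestamps beat times in seconds (absolute clock), strictly
#'   increasing.
#' @param axis_of_origin "aZ", "gX" or "fused".
#' @param min_spacing minimum spacing enforced at detection time, seconds
#'   (recorded for provenance; `NA` when not applicable).
#' @return list of class `beat_list` with `timestamps`, `axis_of_origin`,
#'   `min_spacing` and derived `btb_s` (successive differences).
#' @export
beat_list <- function(timestamps, axis_of_origin = "fused",
                      min_spacing = NA_real_) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("beat timestamps must be strictly increasing")
  structure(list(timestamps = timestamps, axis_of_origin = axis_of_origin,
                 min_spacing = min_spacing,
                 btb_s = diff(timestamps)),
            class = "beat_list")
}

#' @export
print.beat_list <- function(x, ...) {
  cat(sprintf("<beat_list> %d beats (%s)", length(x$timestamps),
              x$axis_of_origin))
  if (length(x$btb_s))
    cat(sprintf(", median BTB %.3f s", stats::median(x$btb_s)))
  cat("\n")
  invisible(x)
}

#' Detect aortic-opening candidates in an enhanced waveform
#'
#' Local maxima of the beat-variant VarWin output are admitted greedily in
#' descending amplitude (ties broken by the earlier timestamp) subject to a
#' pairwise spacing of at least `min_frac` of the average beat-to-beat
#' interval implied by the supplied heart rate. The averaged HR thus acts as
#' a spacing prior that rejects second-heart-sound (AC) peaks, which fall
#' well inside 75% of a beat interval from the neighbouring AO peak and are
#' enhanced less.
#'
#' Because the beat-variant window is forward-looking, the enhancement peaks
#' ahead of the AO point itself. When the underlying (high-pass filtered)
#' waveform is supplied via `raw`, each admitted candidate is therefore
#' refined to the raw-signal maximum inside the forward span it scanned —
#' the AO fiducial peak proper — which pins the timestamp to the same
#' physical landmark on both the aZ and -gX axes so that the 25 ms
#' cross-verification compares like with like.
#'
#' @param enh an `enhanced_signal` (beat variant).
#' @param hr_bpm averaged heart rate prior in bpm; `NA` yields an empty
#'   result (the beat stage requires the HR prior).
#' @param min_frac minimum spacing as a fraction of `60/hr_bpm` seconds
#'   (default 0.75).
#' @param raw optional [uniform_signal()] the enhancement was computed from;
#'   enables refinement of candidate timestamps to the AO peak.
#' @return numeric vector of absolute candidate timestamps, sorted.
#' @export
detect_ao_candidates <- function(enh, hr_bpm, min_frac = 0.75, raw = NULL) {
  if (is.na(hr_bpm)) return(numeric(0))
  stopifnot(hr_bpm > 0, min_frac > 0)
  x <- enh$values
  ex <- local_extrema(x)
  pk <- which(ex$max & x > 0)
  ## a leading plateau that the signal then falls away from is a peak for
  ## detection purposes (it happens when a beat's enhancement is already
  ## maximal at the analysis-window start); interior plateaus are handled
  ## by the three-point rule
  r <- rle(x)
  if (length(r$values) >= 2 && r$values[1] > r$values[2] && x[1] > 0)
    pk <- c(1L, pk)
  if (!length(pk)) return(numeric(0))
  min_sp <- min_frac * 60 / hr_bpm
  span <- round(enh$span_ms / 1000 * enh$fs)
  ord <- pk[order(-x[pk], pk)]
  taken <- numeric(0)
  for (i in seq_along(ord)) {
    ti <- enh$t0 + (ord[i] - 1) / enh$fs
    if (!is.null(raw)) {
      k0 <- round((ti - raw$t0) * raw$fs) + 1L
      k1 <- min(length(raw$values), k0 + span)
      k0 <- max(1L, k0)
      if (k1 >= k0) ti <- raw$t0 + (k0 + which.max(raw$values[k0:k1]) - 2L) / raw$fs
    }
    if (!length(taken) || all(abs(taken - ti) >= min_sp))
      taken <- c(taken, ti)
  }
  sort(taken)
}

#' Consolidate beat candidates reported by multiple windows
#'
#' The same AO event is typically detected by several analysis windows at
#' slightly different timestamps. Candidates are pooled, sorted, and
#' single-linkage clustered: a gap larger than `dedupe_tol` starts a new
#' cluster, and each cluster is reduced to its centroid.
#'
#' @param per_window list of sorted timestamp vectors.
#' @param dedupe_tol merge tolerance in seconds (default 0.1).
#' @return sorted numeric vector of consolidated timestamps.
#' @export
consolidate_candidates <- function(per_window, dedupe_tol = 0.1) {
  .consolidate_support(per_window, dedupe_tol)$ts
}

## as consolidate_candidates, but also report how many raw candidates
## backed each cluster (its "support")
.consolidate_support <- function(per_window, dedupe_tol = 0.1) {
  all_ts <- sort(unlist(per_window, use.names = FALSE))
  if (!length(all_ts)) return(list(ts = numeric(0), support = integer(0)))
  grp <- cumsum(c(1, as.integer(diff(all_ts) > dedupe_tol)))
  list(ts = as.numeric(tapply(all_ts, grp, mean)),
       support = as.integer(tapply(all_ts, grp, length)))
}

#' Cross-verify SCG beats against the gyroscope axis
#'
#' Only SCG AO timestamps with a GCG peak within `tol` seconds are retained
#' (SCG timing stays authoritative); each GCG peak can vouch for at most one
#' SCG beat, nearest pairs first. The gyroscope never injects beats — it
#' only vetoes — so the result is always a subset of the SCG candidates.
#'
#' @param scg_ts,gcg_ts sorted timestamp vectors.
#' @param tol verification tolerance in seconds (default 0.025).
#' @param min_spacing recorded in the returned [beat_list()].
#' @return a [beat_list()] of the retained SCG timestamps
#'   (`axis_of_origin = "fused"`).
#' @export
cross_verify <- function(scg_ts, gcg_ts, tol = 0.025,
                         min_spacing = NA_real_) {
  if (!length(scg_ts) || !length(gcg_ts))
    return(beat_list(numeric(0), "fused", min_spacing))
  pairs <- NULL
  for (i in seq_along(scg_ts)) {
    d <- abs(gcg_ts - scg_ts[i])
    j <- which(d <= tol)
    if (length(j)) pairs <- rbind(pairs, cbind(i = i, j = j, d = d[j]))
  }
  if (is.null(pairs)) return(beat_list(numeric(0), "fused", min_spacing))
  pairs <- pairs[order(pairs[, "d"], pairs[, "i"]), , drop = FALSE]
  used_i <- logical(length(scg_ts))
  used_j <- logical(length(gcg_ts))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, "i"]; j <- pairs[k, "j"]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE
      used_j[j] <- TRUE
    }
  }
  beat_list(scg_ts[used_i], "fused", min_spacing)
}

#' Instantaneous heart rate from beat-to-beat intervals
#'
#' @param beats a [beat_list()].
#' @return list of class `instant_hr_series` with `times` (the later beat of
#'   each pair, seconds) and `hr_bpm` (`60 / btb_s`); empty with fewer than
#'   two beats.
#' @export
instantaneous_hr <- function(beats) {
  ts <- beats$timestamps
  if (length(ts) < 2)
    return(structure(list(times = numeric(0), hr_bpm = numeric(0)),
                     class = "instant_hr_series"))
  structure(list(times = ts[-1], hr_bpm = 60 / diff(ts)),
            class = "instant_hr_series")
}

#' Write / read beat annotations
#'
#' `write_beats()` emits a two-column CSV (`timestamp_s`,
#' `instantaneous_hr_bpm`; the first row's rate is empty) and, when `ann`
#' is given, a plain annotation file with one timestamp per line.
#'
#' @param beats a [beat_list()].
#' @param path output CSV path.
#' @param ann optional plain-text annotation path.
#' @return `path` invisibly.
#' @export
write_beats <- function(beats, path, ann = NULL) {
  ts <- beats$timestamps
  hr <- c(NA_real_, if (length(ts) > 1) 60 / diff(ts))
  df <- data.frame(timestamp_s = sprintf("%.6f", ts),
                   instantaneous_hr_bpm = ifelse(is.na(hr), "",
                                                 sprintf("%.4f", hr)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(ann)) writeLines(sprintf("%.6f", ts), ann)
  invisible(path)
}

#' @rdname write_beats
#' @export
read_beat_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.numeric(readLines(path))
}
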