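#' Construct an R-peak list
#'
#' @param timestamps R-peak times in seconds, strictly increasing.
#' @return list of class `r_peak_list` with `timestamps` and `rr_s`
#'   (successive differences).
#' @export
r_peak_list <- function(timestamps) {
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("R-peak timestamps must be strictly increasing")
  structure(list(timestamps = timestamps, rr_s = diff(timestamps)),
            class = "r_peak_list")
}

## peak slope of the integrated waveform in a +/- 75 ms neighbourhood,
## used for the Pan-Tompkins T-wave discrimination test
.pt_slope <- function(integ, idx, fs) {
  w <- round(0.075 * fs)
  lo <- max(2, idx - w)
  hi <- min(length(integ), idx + w)
  max(abs(diff(integ[lo:hi])))
}

#' Pan-Tompkins QRS detection
#'
#' Canonical real-time QRS detector used as the ECG timing reference:
#' 5–15 Hz band-pass (realised as a zero-phase second-order Butterworth
#' cascade, so no group-delay correction is needed), five-point derivative,
#' squaring, 150 ms moving-window integration, then dual adaptive thresholds
#' on the integrated waveform with a 200 ms refractory period, T-wave
#' discrimination (a candidate within 360 ms of the previous QRS whose peak
#' slope is less than half of the previous one is rejected as a T wave) and
#' a 1.66-times-average-RR search-back with the lower threshold. Signal and
#' noise levels are learnt over the first 2 s. Each accepted detection is
#' finally refined to the raw-signal local maximum within 50 ms.
#'
#' @param ecg a [uniform_signal()] holding the ECG channel.
#' @param fs sampling rate (defaults to `ecg$fs`); at least 100 Hz is
#'   recommended.
#' @return an [r_peak_list()] (empty for flat signals).
#' @export
pan_tompkins <- function(ecg, fs = ecg$fs) {
  stopifnot(inherits(ecg, "uniform_signal"))
  x <- ecg$values
  n <- length(x)
  if (n < 2 * fs) stop("signal length must be at least 2 s")
  if (max(x) - min(x) <= 0) return(r_peak_list(numeric(0)))

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- as.numeric(signal::filtfilt(bf, x))
  d <- stats::filter(xb, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- max(1L, round(0.15 * fs))
  integ <- stats::filter(sq, rep(1 / w, w), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  ex <- local_extrema(integ)
  pk <- which(ex$max)
  if (!length(pk)) return(r_peak_list(numeric(0)))
  ## one fiducial candidate per 200 ms neighbourhood: the integration lobe
  ## of a single QRS carries several ripple maxima, keep only the tallest
  refr <- round(0.2 * fs)
  ord <- pk[order(-integ[pk], pk)]
  kept <- integer(0)
  for (p in ord)
    if (!length(kept) || all(abs(kept - p) > refr)) kept <- c(kept, p)
  pk <- sort(kept)

  learn <- integ[seq_len(min(n, round(2 * fs)))]
  spki <- 0.25 * max(learn)
  npki <- 0.5 * mean(learn)
  twin <- round(0.36 * fs)

  qrs <- integer(0)
  qrs_slope <- numeric(0)
  rr <- numeric(0)
  for (p in pk) {
    thr1 <- npki + 0.25 * (spki - npki)
    since <- if (length(qrs)) p - qrs[length(qrs)] else Inf
    if (integ[p] >= thr1) {
      slope <- .pt_slope(integ, p, fs)
      if (since <= twin && length(qrs_slope) &&
          slope < 0.5 * qrs_slope[length(qrs_slope)]) {
        npki <- 0.125 * integ[p] + 0.875 * npki   # T wave
        next
      }
      if (length(qrs)) rr <- c(rr, since / fs)
      qrs <- c(qrs, p)
      qrs_slope <- c(qrs_slope, slope)
      spki <- 0.125 * integ[p] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
      ## search-back: a long pause suggests a missed low-amplitude QRS
      rr_avg <- if (length(rr)) mean(utils::tail(rr, 8)) else NA_real_
      if (length(qrs) && !is.na(rr_avg) && since > 1.66 * rr_avg * fs) {
        seg <- pk[pk > qrs[length(qrs)] + refr & pk < p]
        seg <- seg[integ[seg] >= 0.5 * thr1]
        if (length(seg)) {
          b <- seg[which.max(integ[seg])]
          rr <- c(rr, (b - qrs[length(qrs)]) / fs)
          qrs <- c(qrs, b)
          qrs_slope <- c(qrs_slope, .pt_slope(integ, b, fs))
          spki <- 0.25 * integ[b] + 0.75 * spki
        }
      }
    }
  }
  if (!length(qrs)) return(r_peak_list(numeric(0)))
  qrs <- sort(unique(qrs))

  ## refine to the raw-signal local maximum within +/- 50 ms
  half <- round(0.05 * fs)
  ref <- vapply(qrs, function(p) {
    lo <- max(1L, as.integer(p - half))
    hi <- min(n, as.integer(p + half))
    lo + which.max(x[lo:hi]) - 1L
  }, numeric(1))
  ref <- sort(unique(ref))
  ## enforce the refractory period on the refined peaks (keep the earlier)
  if (length(ref) > 1) {
    out <- ref[1]
    for (p in ref[-1]) if (p - out[length(out)] > refr) out <- c(out, p)
    ref <- out
  }
  r_peak_list(ecg$t0 + (ref - 1) / fs)
}

#' Write R-peak annotations (one timestamp per line)
#'
#' @param peaks an [r_peak_list()].
#' @param path output text path.
#' @return `path` invisibly.
#' @export
write_rpeaks <- function(peaks, path) {
  writeLines(sprintf("%.6f", peaks$timestamps), path)
  invisible(path)
}
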