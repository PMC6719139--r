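#' Construct a uniformly sampled signal
#'
#' @param values numeric amplitude vector (channel units).
#' @param fs sampling rate, Hz.
#' @param t0 absolute time of the first sample, seconds.
#' @param channel_id axis label, e.g. "aZ".
#' @return an object of class `uniform_signal`. Implied sample times are
#'   `t0 + (k - 1)/fs`.
#' @export
uniform_signal <- function(values, fs, t0 = 0, channel_id = "") {
  stopifnot(fs > 0, length(values) >= 2)
  structure(list(values = as.numeric(values), fs = fs, t0 = t0,
                 channel_id = channel_id),
            class = "uniform_signal")
}

#' Sample times of a uniform signal
#' @param sig a `uniform_signal` (or `enhanced_signal`).
#' @return absolute times in seconds.
#' @export
signal_times <- function(sig) {
  sig$t0 + (seq_along(sig$values) - 1) / sig$fs
}

#' Resample a buffered channel onto a uniform grid
#'
#' Irregular (jittered) sample times are reorganised onto a uniform grid by
#' shape-preserving piecewise-cubic Hermite (pchip) interpolation, which is
#' monotone between nodes and therefore never overshoots the local data
#' envelope. The grid spans `ceil(first * fs)/fs` to `floor(last * fs)/fs`,
#' both ends inclusive, so no extrapolation occurs.
#'
#' @param seg a [buffer_segment()] or `raw_recording`.
#' @param channel channel id to resample, e.g. "aZ".
#' @param target_fs target sampling rate, Hz (default 200).
#' @return a [uniform_signal()].
#' @export
resample_uniform <- function(seg, channel, target_fs = 200) {
  rec <- if (inherits(seg, "buffer_segment")) seg$recording else seg
  if (!channel %in% names(rec$channels))
    stop("channel not present: ", channel)
  t <- rec$timestamps
  y <- rec$channels[[channel]]
  if (length(t) < 4)
    stop("insufficient data: pchip interpolation needs at least 4 samples")
  k0 <- ceiling(t[1] * target_fs)
  k1 <- floor(t[length(t)] * target_fs)
  if (k1 - k0 < 1) stop("insufficient data: segment spans fewer than 2 grid points")
  grid <- (k0:k1) / target_fs
  vals <- pracma::pchip(t, y, grid)
  uniform_signal(vals, target_fs, t0 = k0 / target_fs, channel_id = channel)
}

#' Ideal (brick-wall) high-pass filter
#'
#' Removes all frequency content strictly below `cutoff` by zeroing the
#' corresponding DFT bins of the analysis window and inverting the
#' transform, realising an ideal response over the buffer; block processing
#' matches the rolling-buffer architecture. Before the transform, the line
#' through the window's endpoints is subtracted (bridge detrending): the DFT
#' treats the buffer as circular, and the first-to-last sample jump caused
#' by slow baseline wander would otherwise ring across the buffer edges.
#' The removed line is itself sub-cutoff (trend) content, so it is not added
#' back. The DC bin is always removed and the output mean is numerically
#' zero.
#'
#' @param sig a [uniform_signal()].
#' @param cutoff cutoff frequency in Hz, must be below Nyquist (default 0.4).
#' @return a [uniform_signal()] with the same `fs`, `t0` and `channel_id`.
#' @export
highpass_brickwall <- function(sig, cutoff = 0.4) {
  stopifnot(inherits(sig, "uniform_signal"))
  if (cutoff >= sig$fs / 2) stop("cutoff must be below the Nyquist frequency")
  x <- sig$values
  n <- length(x)
  bridge <- x[1] + (x[n] - x[1]) * (0:(n - 1)) / (n - 1)
  X <- stats::fft(x - bridge)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * sig$fs / n
  X[freq < cutoff] <- 0
  out <- Re(stats::fft(X, inverse = TRUE)) / n
  out <- out - mean(out)
  uniform_signal(out, sig$fs, sig$t0, sig$channel_id)
}
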