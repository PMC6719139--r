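#' Locate strict local extrema
#'
#' Three-point strict comparison with plateau handling: runs of equal values
#' are compressed and a run counts as a local maximum (minimum) when both
#' neighbouring runs are lower (higher); the extremum index is the first
#' sample of the run. The first and last runs are never extrema.
#'
#' @param x numeric vector.
#' @return list with logical vectors `max` and `min`, same length as `x`.
#' @export
local_extrema <- function(x) {
  n <- length(x)
  ismax <- logical(n)
  ismin <- logical(n)
  if (n < 3) return(list(max = ismax, min = ismin))
  r <- rle(x)
  m <- length(r$values)
  if (m >= 3) {
    starts <- cumsum(c(1L, r$lengths[-m]))
    v <- r$values
    j <- 2:(m - 1)
    maxrun <- j[v[j] > v[j - 1] & v[j] > v[j + 1]]
    minrun <- j[v[j] < v[j - 1] & v[j] < v[j + 1]]
    ismax[starts[maxrun]] <- TRUE
    ismin[starts[minrun]] <- TRUE
  }
  list(max = ismax, min = ismin)
}

## Sliding max/min over the window x[i + lo .. i + hi] (clamped to the
## signal), for every i. van Herk / Gil-Werman two-scan algorithm: the padded
## signal is cut into blocks of the window length; blockwise forward and
## backward cumulative extrema then give each window extremum as the
## combination of two precomputed values. Comparison-only, so results are
## bit-identical to a naive scan.
roll_extreme <- function(x, lo, hi, type = c("max", "min")) {
  type <- match.arg(type)
  n <- length(x)
  k <- hi - lo + 1
  stopifnot(k >= 1)
  pad <- if (type == "max") -Inf else Inf
  P <- max(0L, -lo)
  Q <- max(0L, hi)
  xp <- c(rep(pad, P), x, rep(pad, Q))
  m <- length(xp)
  extra <- (k - (m %% k)) %% k
  if (extra) xp <- c(xp, rep(pad, extra))
  mat <- matrix(xp, nrow = k)
  cfun <- if (type == "max") cummax else cummin
  L <- as.vector(apply(mat, 2, cfun))
  R <- as.vector(apply(mat[k:1, , drop = FALSE], 2, cfun)[k:1, , drop = FALSE])
  starts <- (1 + lo + P) + seq_len(n) - 1L
  ends <- starts + k - 1L
  if (type == "max") pmax(R[starts], L[ends]) else pmin(R[starts], L[ends])
}

## rolling "does the window contain a TRUE" over offsets [lo, hi]
roll_any <- function(flag, lo, hi) {
  if (hi < lo) return(rep(FALSE, length(flag)))
  roll_extreme(as.numeric(flag), lo, hi, "max") > 0
}

new_enhanced_signal <- function(values, src, variant, span_ms) {
  structure(list(values = values, fs = src$fs, t0 = src$t0,
                 channel_id = src$channel_id, variant = variant,
                 span_ms = span_ms),
            class = c("enhanced_signal", "uniform_signal"))
}

varwin_span_samples <- function(sig, span_ms) {
  s <- round(span_ms / 1000 * sig$fs)
  if (s < 3) stop("VarWin span shorter than 3 samples")
  if (length(sig$values) <= s)
    stop("signal must be longer than the VarWin span")
  s
}

#' VarWin oscillation amplifier, heart-rate variant
#'
#' The irreversible transfer function at the heart of the averaged-HR path.
#' At each sample it scans a centred window of about `span_ms` for large
#' amplitude oscillations: the output is the windowed range (max minus min)
#' gated to zero unless the window interior contains at least one strict
#' local maximum AND one strict local minimum. A peak in the output therefore
#' marks the co-occurrence of both extrema within the span — the signature of
#' the S1 (AO/IC) oscillation complex — while smooth trends map to zero.
#'
#' The window at sample i covers offsets `[-h, +h]` with
#' `h = floor(span_samples/2)`, clamped at the signal edges; "interior" means
#' offsets `[-h+1, +h-1]`.
#'
#' @param sig a [uniform_signal()].
#' @param span_ms oscillation scan span in milliseconds (default 250).
#' @return an `enhanced_signal` (non-negative, same length/fs/t0 as `sig`).
#' @export
varwin_hr <- function(sig, span_ms = 250) {
  s <- varwin_span_samples(sig, span_ms)
  h <- max(1L, floor(s / 2))
  x <- sig$values
  rng <- roll_extreme(x, -h, h, "max") - roll_extreme(x, -h, h, "min")
  ex <- local_extrema(x)
  gate <- roll_any(ex$max, -(h - 1L), h - 1L) &
          roll_any(ex$min, -(h - 1L), h - 1L)
  new_enhanced_signal(rng * gate, sig, "hr", span_ms)
}

#' VarWin oscillation amplifier, beat-identification variant
#'
#' Modified transfer function used for aortic-opening (AO) beat timing. Two
#' changes relative to [varwin_hr()]:
#' \itemize{
#' \item the variation window is strictly forward-looking — offsets
#'   `[0, +span]` — so the enhancement rises ahead of each oscillation
#'   complex and the leading AO edge is emphasised over trailing structure;
#' \item output directly after a deep local minimum is suppressed to zero,
#'   which attenuates features that ride on the recovery from a trough: the
#'   rapid-ejection (RE) peak after the IC minimum, and — because the whole
#'   lead-in falls inside the suppression span — the aortic-closing /
#'   mitral-opening (AC–MO, second heart sound) complex that trails the IC
#'   minimum by a systolic interval.
#' }
#' "Deep" means the minimum's value lies within the bottom
#' `min_depth_frac` of the signal's amplitude range; without this guard,
#' broadband noise would scatter suppressing minima everywhere. Both the
#' gating and suppression compare amplitudes relatively, so the output
#' scales linearly with the input and ignores constant offsets.
#'
#' @param sig a [uniform_signal()] (for gyrocardiography pass the negated
#'   gX axis, whose beat complex then points the same way as aZ).
#' @param span_ms forward scan span in milliseconds (default 250).
#' @param suppress_ms suppression span after a deep local minimum,
#'   milliseconds. Defaults to `span_ms`; the beat pipeline shortens it to a
#'   fraction of the prevailing beat-to-beat interval at high heart rates.
#' @param min_depth_frac depth threshold for suppressing minima, as a
#'   fraction of the signal amplitude range (default 0.3).
#' @return an `enhanced_signal` with `variant = "beat"`.
#' @export
varwin_beat <- function(sig, span_ms = 250, suppress_ms = span_ms,
                        min_depth_frac = 0.3) {
  s <- varwin_span_samples(sig, span_ms)
  x <- sig$values
  rng <- roll_extreme(x, 0L, s, "max") - roll_extreme(x, 0L, s, "min")
  ex <- local_extrema(x)
  gate <- roll_any(ex$max, 1L, s - 1L) & roll_any(ex$min, 1L, s - 1L)
  lo <- min(x)
  amp <- max(x) - lo
  deep <- ex$min & (x <= lo + min_depth_frac * amp)
  ss <- max(1L, round(suppress_ms / 1000 * sig$fs))
  sup <- roll_any(deep, -ss, -1L)
  new_enhanced_signal(rng * gate * !sup, sig, "beat", span_ms)
}
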