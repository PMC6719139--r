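## last n_seconds of a (possibly enhanced) uniform signal
tail_signal <- function(sig, n_seconds) {
  n <- length(sig$values)
  k <- min(n, round(n_seconds * sig$fs))
  out <- sig
  out$values <- sig$values[(n - k + 1):n]
  out$t0 <- sig$t0 + (n - k) / sig$fs
  out
}

## unbiased linear autocorrelation of a mean-removed vector, lags 0..n-1,
## computed by zero-padded FFT
autocorr_unbiased <- function(x) {
  n <- length(x)
  m <- stats::nextn(2 * n, 2)
  X <- stats::fft(c(x, rep(0, m - n)))
  c_full <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / m
  c_full[1:n] / (n - 0:(n - 1))
}

#' Heart-rate estimate from one analysis window
#'
#' Autocorrelates the mean-removed enhanced waveform and reads the dominant
#' beat-to-beat (BTB) lag off its harmonic structure. Candidate lags are
#' local autocorrelation maxima inside the physiological range
#' `[60/bounds2, 60/bounds1]` seconds whose height reaches
#' `prominence_floor` times the zero-lag value. Among candidates, the
#' shortest lag whose integer multiples (within `harmonic_tol` relative
#' tolerance) are all also candidate peaks is preferred — the spacing of the
#' harmonics, not the tallest peak, judges the BTB, which resists
#' half-rate/double-rate errors. If no candidate's harmonic train is
#' complete, the most prominent candidate is used. Lags beyond half the
#' window length are not searched (the unbiased estimator is too noisy
#' there), so short windows legitimately return an absent estimate at low
#' heart rates.
#'
#' @param enh an `enhanced_signal` (or any [uniform_signal()]).
#' @param bounds physiological heart-rate bounds in bpm, default
#'   `c(30, 200)`.
#' @param prominence_floor fraction of the zero-lag autocorrelation a peak
#'   must reach (default 0.3).
#' @param harmonic_tol relative tolerance for harmonic matching
#'   (default 0.05).
#' @return a list of class `window_estimate` with `window_s`, `axis`,
#'   `hr_bpm` (NA when absent), `btb_s`, `confidence` (peak height relative
#'   to zero lag). `hr_bpm = 60/btb_s` whenever present.
#' @export
hr_from_window <- function(enh, bounds = c(30, 200), prominence_floor = 0.3,
                           harmonic_tol = 0.05) {
  stopifnot(length(bounds) == 2)
  if (bounds[1] >= bounds[2]) stop("inverted heart-rate bounds")
  est <- structure(list(window_s = length(enh$values) / enh$fs,
                        axis = enh$channel_id,
                        hr_bpm = NA_real_, btb_s = NA_real_,
                        confidence = NA_real_),
                   class = "window_estimate")
  x <- enh$values - mean(enh$values)
  n <- length(x)
  if (n < 8 || max(abs(x)) == 0) return(est)
  r <- autocorr_unbiased(x)
  r0 <- r[1]
  if (!is.finite(r0) || r0 <= 0) return(est)
  fs <- enh$fs
  lmin <- max(2L, ceiling(fs * 60 / bounds[2]))
  lmax <- min(floor(fs * 60 / bounds[1]), floor(n / 2))
  if (lmax - lmin < 2) return(est)
  lags <- (lmin + 1):(lmax - 1)
  ispeak <- r[lags + 1] > r[lags] & r[lags + 1] >= r[lags + 2]
  cand <- lags[ispeak & r[lags + 1] >= prominence_floor * r0]
  if (!length(cand)) return(est)
  harmonic_ok <- function(L) {
    mult <- 2
    while (mult * L <= lmax) {
      if (!any(abs(cand - mult * L) <= harmonic_tol * mult * L)) return(FALSE)
      mult <- mult + 1
    }
    TRUE
  }
  qual <- cand[vapply(cand, harmonic_ok, logical(1))]
  L <- if (length(qual)) qual[1] else cand[which.max(r[cand + 1])]
  btb <- L / fs
  hr <- 60 / btb
  if (hr < bounds[1] || hr > bounds[2]) return(est)
  est$hr_bpm <- hr
  est$btb_s <- btb
  est$confidence <- r[L + 1] / r0
  est
}

#' Fuse per-window heart-rate estimates for one axis
#'
#' Weighted mean of the present estimates with weights inversely
#' proportional to the window size, so short windows — which track the most
#' recent beats — dominate. Weights are renormalised over the windows that
#' produced an estimate.
#'
#' @param estimates list of [hr_from_window()] results sharing one axis.
#' @return fused heart rate in bpm, or `NA_real_` when every window was
#'   absent.
#' @export
fuse_windows <- function(estimates) {
  if (!length(estimates)) return(NA_real_)
  ax <- unique(vapply(estimates, function(e) e$axis, character(1)))
  if (length(ax) > 1) stop("mixed axes in fuse_windows: ", paste(ax, collapse = ", "))
  hr <- vapply(estimates, function(e) e$hr_bpm, numeric(1))
  w <- 1 / vapply(estimates, function(e) e$window_s, numeric(1))
  ok <- !is.na(hr)
  if (!any(ok)) return(NA_real_)
  sum(hr[ok] * w[ok]) / sum(w[ok])
}

#' Consolidate SCG and GCG heart rates into one measurement
#'
#' Decision rule for the dual-modality measurement: when both axes report
#' and agree within `tolerance` bpm, the measurement is cross-verified and
#' the two are averaged. When they disagree, the previous measurement — the
#' last known heart rate, trusted because consecutive 1 s refreshes of a
#' quasi-periodic rhythm change little — arbitrates: the closer result wins
#' (SCG on an exact tie, and also when no previous rate exists, reflecting
#' the higher accuracy of the SCG path). A single reporting axis passes
#' through; if neither axis reports, the previous rate is carried forward
#' when available.
#'
#' @param hr_scg,hr_gcg per-axis fused rates in bpm, `NA` when absent.
#' @param prev_hr previous measurement in bpm, `NA` before initialisation.
#' @param tolerance agreement tolerance in bpm (default 10).
#' @param time refresh instant in seconds (carried into the result).
#' @return list of class `hr_measurement` with `time`, `hr_bpm`, `hr_scg`,
#'   `hr_gcg`, `source` (one of "both-agree", "scg-selected",
#'   "gcg-selected", "carry-forward", "none") and `prev_hr`.
#' @export
consolidate_axes <- function(hr_scg, hr_gcg, prev_hr = NA_real_,
                             tolerance = 10, time = NA_real_) {
  stopifnot(tolerance > 0)
  s_ok <- !is.na(hr_scg)
  g_ok <- !is.na(hr_gcg)
  p_ok <- !is.na(prev_hr)
  if (s_ok && g_ok) {
    if (abs(hr_scg - hr_gcg) <= tolerance) {
      hr <- (hr_scg + hr_gcg) / 2
      src <- "both-agree"
    } else if (p_ok && abs(hr_gcg - prev_hr) < abs(hr_scg - prev_hr)) {
      hr <- hr_gcg
      src <- "gcg-selected"
    } else {
      hr <- hr_scg         # closer to prev, tied, or no previous reference
      src <- "scg-selected"
    }
  } else if (s_ok) {
    hr <- hr_scg
    src <- "scg-selected"
  } else if (g_ok) {
    hr <- hr_gcg
    src <- "gcg-selected"
  } else if (p_ok) {
    hr <- prev_hr
    src <- "carry-forward"
  } else {
    hr <- NA_real_
    src <- "none"
  }
  structure(list(time = time, hr_bpm = hr, hr_scg = hr_scg, hr_gcg = hr_gcg,
                 source = src, prev_hr = prev_hr),
            class = "hr_measurement")
}
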