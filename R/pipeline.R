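## Shared per-buffer processing for the HR and beat stages.
## Returns NULL for an axis whose channel is absent or unusable.
.prep_axis <- function(seg, axis, cfg) {
  rec <- seg$recording
  if (!axis %in% names(rec$channels)) return(NULL)
  sig <- tryCatch(resample_uniform(seg, axis, cfg$target_fs),
                  error = function(e) NULL)
  if (is.null(sig)) return(NULL)
  if (axis == "gX") sig$values <- -sig$values  # beat complex points along -gX
  tryCatch(highpass_brickwall(sig, cfg$highpass_hz), error = function(e) NULL)
}

.axis_hr <- function(hp, cfg) {
  if (is.null(hp)) return(list(fused = NA_real_, enh = NULL))
  span_samp <- round(cfg$varwin_span_ms / 1000 * hp$fs)
  if (length(hp$values) <= span_samp) return(list(fused = NA_real_, enh = NULL))
  enh <- varwin_hr(hp, cfg$varwin_span_ms)
  ests <- list()
  for (n in cfg$windows_s) {
    if (round(n * enh$fs) < 8) next
    e <- hr_from_window(tail_signal(enh, n), bounds = cfg$hr_bounds,
                        prominence_floor = cfg$prominence_floor,
                        harmonic_tol = cfg$harmonic_tol)
    ests[[length(ests) + 1]] <- e
  }
  list(fused = fuse_windows(ests), enh = enh)
}

.axis_beats <- function(hp, hr_prior, cfg) {
  if (is.null(hp) || is.na(hr_prior)) return(NULL)
  btb <- 60 / hr_prior
  supp_ms <- min(cfg$varwin_span_ms, cfg$suppress_frac * btb * 1000)
  enh <- varwin_beat(hp, cfg$varwin_span_ms, suppress_ms = supp_ms,
                     min_depth_frac = cfg$min_depth_frac)
  per_win <- lapply(cfg$windows_s, function(n)
    detect_ao_candidates(tail_signal(enh, n), hr_prior, cfg$min_frac,
                         raw = tail_signal(hp, n)))
  consolidate_candidates(per_win, cfg$dedupe_tol)
}

.process_buffer <- function(seg, prev_hr, cfg) {
  scg_hp <- .prep_axis(seg, "aZ", cfg)
  gcg_hp <- .prep_axis(seg, "gX", cfg)
  hr_scg <- .axis_hr(scg_hp, cfg)$fused
  hr_gcg <- .axis_hr(gcg_hp, cfg)$fused
  hrm <- consolidate_axes(hr_scg, hr_gcg, prev_hr,
                          tolerance = cfg$hr_tolerance,
                          time = seg$window_end)
  scg_ts <- .axis_beats(scg_hp, if (is.na(hr_scg)) hrm$hr_bpm else hr_scg, cfg)
  gcg_ts <- .axis_beats(gcg_hp, if (is.na(hr_gcg)) hrm$hr_bpm else hr_gcg, cfg)
  min_sp <- if (!is.na(hrm$hr_bpm)) cfg$min_frac * 60 / hrm$hr_bpm else NA_real_
  beats <- if (!is.null(scg_ts) && !is.null(gcg_ts)) {
    cross_verify(scg_ts, gcg_ts, cfg$cross_tol, min_sp)
  } else if (!is.null(scg_ts) && is.null(gcg_hp) && cfg$permissive_gcg) {
    beat_list(scg_ts, "aZ", min_sp)
  } else {
    beat_list(numeric(0), "fused", min_sp)
  }
  list(hr = hrm, beats = beats)
}

#' Run the averaged-HR pipeline on one buffer
#'
#' Orchestrates, for a single rolling buffer: resampling of aZ and -gX to
#' the target rate, brick-wall high-pass, VarWin enhancement, per-window
#' autocorrelation HR over all configured window sizes, inverse-window-size
#' weighted fusion per axis, and SCG/GCG consolidation against the previous
#' measurement. Missing channels degrade gracefully to single-axis (or
#' absent) measurements.
#'
#' @param seg a [buffer_segment()].
#' @param prev previous [consolidate_axes()] measurement (or `NULL` / its
#'   `hr_bpm`); used as the feedback reference.
#' @param cfg an [ada_config()].
#' @return an `hr_measurement`.
#' @export
run_hr_pipeline <- function(seg, prev = NULL, cfg = ada_config()) {
  prev_hr <- if (is.null(prev)) NA_real_
             else if (inherits(prev, "hr_measurement")) prev$hr_bpm
             else as.numeric(prev)
  .process_buffer(seg, prev_hr, cfg)$hr
}

#' Detect heart rate and beats over a whole recording
#'
#' Replays the recording through the rolling-buffer front end and runs the
#' full dual-modality pipeline at each refresh instant: averaged HR per
#' buffer (with previous-measurement feedback, initialised by the first
#' cross-verified agreement), beat-variant VarWin AO candidate detection per
#' analysis window, cross-window consolidation, SCG-vs-GCG cross
#' verification, and finally consolidation of per-buffer beats into one
#' global beat list from which the instantaneous heart rate is derived.
#'
#' @param rec a [raw_recording()] with at least one of `aZ`, `gX` (an
#'   `ecg` channel is ignored here; see [pan_tompkins()]).
#' @param cfg an [ada_config()].
#' @return list of class `ada_result`:
#' \describe{
#'   \item{hr}{data.frame of per-refresh measurements (`time`, `hr_bpm`,
#'     `hr_scg`, `hr_gcg`, `source`, `prev_hr`).}
#'   \item{beats}{global [beat_list()] of AO timestamps.}
#'   \item{instant_hr}{[instantaneous_hr()] series of the beat list.}
#'   \item{config}{the configuration used.}
#' }
#' @export
detect_recording <- function(rec, cfg = ada_config()) {
  segs <- stream_buffers(rec, cfg$buffer_span, cfg$step)
  hr_rows <- list()
  buf_beats <- list()
  prev_ref <- NA_real_
  for (seg in segs) {
    out <- .process_buffer(seg, prev_ref, cfg)
    m <- out$hr
    hr_rows[[length(hr_rows) + 1]] <-
      data.frame(time = m$time, hr_bpm = m$hr_bpm, hr_scg = m$hr_scg,
                 hr_gcg = m$hr_gcg, source = m$source, prev_hr = m$prev_hr)
    if (length(out$beats$timestamps))
      buf_beats[[length(buf_beats) + 1]] <- out$beats$timestamps
    ## feedback reference: initialised by the first cross-verified
    ## agreement, then tracks every subsequent non-absent measurement
    if (!is.na(m$hr_bpm) && (m$source == "both-agree" || !is.na(prev_ref)))
      prev_ref <- m$hr_bpm
  }
  cons <- .consolidate_support(buf_beats, cfg$dedupe_tol)
  global_ts <- cons$ts
  ## retained beats must fit the BTB interval indicated by the HR
  ## measurement in their timeframe; clusters seen by more buffers win
  ## conflicts. Falls back to the physiological floor where no HR exists.
  hrdf <- do.call(rbind, hr_rows)
  floor_sp <- 60 / cfg$hr_bounds[2]
  min_sp_at <- function(t) {
    ok <- !is.na(hrdf$hr_bpm)
    if (is.null(hrdf) || !any(ok)) return(floor_sp)
    h <- stats::approx(hrdf$time[ok], hrdf$hr_bpm[ok], xout = t,
                       method = "constant", f = 0, rule = 2)$y
    max(floor_sp, cfg$min_frac * 60 / h)
  }
  if (length(global_ts) > 1) {
    ord <- order(-cons$support, global_ts)
    kept <- numeric(0)
    for (i in ord) {
      sp <- min_sp_at(global_ts[i])
      if (!length(kept) || all(abs(kept - global_ts[i]) >= sp))
        kept <- c(kept, global_ts[i])
    }
    global_ts <- sort(kept)
  }
  beats <- beat_list(global_ts, "fused", floor_sp)
  structure(list(hr = do.call(rbind, hr_rows), beats = beats,
                 instant_hr = instantaneous_hr(beats), config = cfg),
            class = "ada_result")
}

#' @export
print.ada_result <- function(x, ...) {
  hr <- x$hr$hr_bpm
  cat(sprintf("<ada_result> %d refresh instants, %d beats",
              NROW(x$hr), length(x$beats$timestamps)))
  if (any(!is.na(hr)))
    cat(sprintf(", median HR %.1f bpm", stats::median(hr, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

#' Hold-resample an ECG-derived heart rate onto refresh instants
#'
#' Converts reference R peaks to instantaneous HR (inverse R-R) and samples
#' it at the requested times by previous-value hold, mirroring what a 1 Hz
#' display refreshing from the latest completed interval would show.
#'
#' @param peaks an [r_peak_list()].
#' @param times refresh instants, seconds.
#' @return numeric vector of bpm (NA before the first complete interval).
#' @export
reference_hr_series <- function(peaks, times) {
  inst <- instantaneous_hr(beat_list(peaks$timestamps, "aZ"))
  if (!length(inst$times)) return(rep(NA_real_, length(times)))
  stats::approx(inst$times, inst$hr_bpm, xout = times, method = "constant",
                f = 0, rule = 1:2)$y
}

#' Sampling-rate sweep harness
#'
#' Reruns detection and evaluation of one recording at several uniform
#' resampling rates, reporting the accuracy trade-off (no timing is
#' measured; wall-clock cost is hardware-dependent).
#'
#' @param rec a [raw_recording()] with an `ecg` channel for the reference.
#' @param rates resampling rates in Hz (default `c(50, 100, 150, 200, 250)`).
#' @param cfg base [ada_config()]; `target_fs` is overridden per rate.
#' @return data.frame with one row per rate: `fs`, `beats`, `TP`, `FP`,
#'   `FN`, `TPR`, `PPV`, `r2` (instantaneous), `r2_avg` (averaged HR).
#' @export
sweep_rates <- function(rec, rates = c(50, 100, 150, 200, 250),
                        cfg = ada_config()) {
  if (!"ecg" %in% names(rec$channels))
    stop("sampling-rate sweep needs an ecg reference channel")
  ecg <- highpass_brickwall(
    resample_uniform(rec, "ecg", cfg$target_fs), cfg$highpass_hz)
  peaks <- pan_tompkins(ecg)
  rows <- lapply(rates, function(fsr) {
    cfg_r <- cfg
    cfg_r$target_fs <- fsr
    res <- detect_recording(rec, cfg_r)
    ev <- evaluate_detection(res$beats, peaks, cfg$ref_match_tol)
    refhr <- reference_hr_series(peaks, res$hr$time)
    ok <- !is.na(refhr) & !is.na(res$hr$hr_bpm)
    ev$r2_avg <- if (sum(ok) >= 3) agreement(res$hr$hr_bpm[ok], refhr[ok])$r2
                 else NA_real_
    cbind(data.frame(fs = fsr), ev)
  })
  do.call(rbind, rows)
}
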