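#' Default algorithm configuration
#'
#' Collects every tunable parameter of the detection pipeline in one list.
#' Defaults follow the algorithm's characterised operating point: 10 s
#' analysis buffer refreshed every 1 s, resampling to 200 Hz, 0.4 Hz
#' brick-wall high-pass, 250 ms VarWin span, analysis windows of 2..10 s,
#' 10 bpm SCG/GCG agreement tolerance, minimum beat spacing of 75% of the
#' average beat-to-beat interval, 25 ms gyroscope cross-verification
#' tolerance and a 250 ms reference-matching window.
#'
#' @param ... name-value pairs overriding individual defaults.
#'
#' @return A named list of class `ada_config`:
#' \describe{
#'   \item{buffer_span, step}{rolling buffer length and refresh period, s.}
#'   \item{target_fs}{uniform resampling rate, Hz.}
#'   \item{highpass_hz}{brick-wall high-pass cutoff, Hz.}
#'   \item{varwin_span_ms}{VarWin oscillation-scan span, ms.}
#'   \item{windows_s}{analysis window lengths, s (integer vector).}
#'   \item{hr_bounds}{physiological heart-rate search range, bpm.}
#'   \item{prominence_floor}{autocorrelation peak floor, fraction of the
#'     zero-lag value.}
#'   \item{harmonic_tol}{relative tolerance when checking that integer
#'     multiples of a candidate beat lag also show autocorrelation peaks.}
#'   \item{hr_tolerance}{SCG/GCG agreement tolerance, bpm.}
#'   \item{min_frac}{minimum beat spacing as a fraction of the average
#'     beat-to-beat interval.}
#'   \item{suppress_frac}{beat-variant VarWin suppression span after a deep
#'     local minimum, as a fraction of the prior beat-to-beat interval
#'     (capped at `varwin_span_ms`).}
#'   \item{min_depth_frac}{how deep (as a fraction of the window amplitude
#'     range, measured from the minimum) a local minimum must be to trigger
#'     beat-variant suppression.}
#'   \item{dedupe_tol}{cross-window beat consolidation tolerance, s.}
#'   \item{cross_tol}{SCG vs GCG beat cross-verification tolerance, s.}
#'   \item{ref_match_tol}{detection vs ECG reference matching window, s.}
#'   \item{permissive_gcg}{if `TRUE`, SCG beats pass unverified when the
#'     gyroscope channel is absent; strict mode (default) discards them.}
#' }
#' @export
#' @examples
#' cfg <- ada_config(target_fs = 100)
#' cfg$target_fs
ada_config <- function(...) {
  cfg <- list(
    buffer_span      = 10,
    step             = 1,
    target_fs        = 200,
    highpass_hz      = 0.4,
    varwin_span_ms   = 250,
    windows_s        = 2:10,
    hr_bounds        = c(30, 200),
    prominence_floor = 0.3,
    harmonic_tol     = 0.05,
    hr_tolerance     = 10,
    min_frac         = 0.75,
    suppress_frac    = 0.3,
    min_depth_frac   = 0.3,
    dedupe_tol       = 0.1,
    cross_tol        = 0.025,
    ref_match_tol    = 0.25,
    permissive_gcg   = FALSE
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$buffer_span > 0, cfg$step > 0, cfg$target_fs > 0,
            cfg$hr_tolerance > 0, length(cfg$hr_bounds) == 2,
            cfg$hr_bounds[1] < cfg$hr_bounds[2])
  class(cfg) <- "ada_config"
  cfg
}

#' Read / write an algorithm configuration as YAML
#'
#' Only keys known to [ada_config()] are accepted; unknown keys are an error
#' so that typos in config files fail loudly.
#'
#' @param path YAML file path.
#' @return `read_config()` returns an `ada_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(ada_config, vals)
}

#' @rdname read_config
#' @param cfg an `ada_config` list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
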