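#' Match detected beats against a reference within a tolerance window
#'
#' One-to-one matching of detected AO timestamps to reference R-peak
#' timestamps: a detection within `tol` seconds of an unclaimed reference
#' counts as a true positive (TP), leftover detections are false positives
#' (FP) and leftover references false negatives (FN). True negatives are
#' meaningless for event detection and are not counted. The assignment is a
#' maximum-cardinality one-to-one matching (computed by scanning detections
#' in time order and claiming the earliest unclaimed reference within
#' tolerance, which is optimal for interval matching on a line), so
#' `tp + fn` always equals the reference count.
#'
#' @param detected a [beat_list()] or sorted numeric vector of timestamps.
#' @param reference an [r_peak_list()] or sorted numeric vector.
#' @param tol matching tolerance in seconds (default 0.25).
#' @return list of class `eval_counts`: `n_ref`, `tp`, `fp`, `fn`, `tol`,
#'   plus `pairs`, an integer matrix with columns `det`, `ref` giving the
#'   matched index pairs (used for interval pairing downstream).
#' @export
match_beats <- function(detected, reference, tol = 0.25) {
  stopifnot(tol > 0)
  det <- if (inherits(detected, "beat_list")) detected$timestamps else as.numeric(detected)
  ref <- if (inherits(reference, "r_peak_list")) reference$timestamps else as.numeric(reference)
  nd <- length(det)
  nr <- length(ref)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("det", "ref")))
  j <- 1L
  for (i in seq_len(nd)) {
    while (j <= nr && ref[j] < det[i] - tol) j <- j + 1L
    if (j <= nr && abs(ref[j] - det[i]) <= tol) {
      pairs <- rbind(pairs, c(i, j))
      j <- j + 1L
    }
  }
  tp <- nrow(pairs)
  structure(list(n_ref = nr, tp = tp, fp = nd - tp, fn = nr - tp,
                 tol = tol, pairs = pairs),
            class = "eval_counts")
}

#' True positive rate (sensitivity)
#'
#' `TPR = TP / (TP + FN)`: the proportion of reference beats that were
#' correctly identified.
#'
#' @param c an `eval_counts` from [match_beats()] (or a list with `tp`,
#'   `fn`).
#' @return fraction in \[0, 1\].
#' @export
tpr <- function(c) {
  if (c$tp + c$fn <= 0) stop("TPR undefined: no reference beats")
  c$tp / (c$tp + c$fn)
}

#' Positive predictive value (precision)
#'
#' `PPV = TP / (TP + FP)`: the likelihood that a detected beat is correct.
#'
#' @param c an `eval_counts` (or a list with `tp`, `fp`).
#' @return fraction in \[0, 1\].
#' @export
ppv <- function(c) {
  if (c$tp + c$fp <= 0) stop("PPV undefined: no detected beats")
  c$tp / (c$tp + c$fp)
}

#' Pair detected and reference beat-to-beat heart rates
#'
#' For each pair of true-positive beats that are consecutive in both the
#' detected and the reference list (no intervening FP or FN), the inverse
#' AO–AO interval is paired with the corresponding inverse R–R interval.
#' Intervals broken by a missed or spurious beat are dropped, so only
#' intervals measured by both systems are compared.
#'
#' @param detected sorted detected timestamps (or [beat_list()]).
#' @param reference sorted reference timestamps (or [r_peak_list()]).
#' @param counts the [match_beats()] result holding the matched pairs.
#' @return data.frame with columns `time` (the later detected beat),
#'   `detected_bpm`, `reference_bpm`; zero rows with fewer than 2 TP beats.
#' @export
paired_hr_series <- function(detected, reference, counts) {
  det <- if (inherits(detected, "beat_list")) detected$timestamps else as.numeric(detected)
  ref <- if (inherits(reference, "r_peak_list")) reference$timestamps else as.numeric(reference)
  p <- counts$pairs
  empty <- data.frame(time = numeric(0), detected_bpm = numeric(0),
                      reference_bpm = numeric(0))
  if (is.null(p) || nrow(p) < 2) return(empty)
  k <- seq_len(nrow(p) - 1)
  ok <- p[k + 1, "det"] == p[k, "det"] + 1L & p[k + 1, "ref"] == p[k, "ref"] + 1L
  if (!any(ok)) return(empty)
  k <- k[ok]
  data.frame(
    time = det[p[k + 1, "det"]],
    detected_bpm = 60 / (det[p[k + 1, "det"]] - det[p[k, "det"]]),
    reference_bpm = 60 / (ref[p[k + 1, "ref"]] - ref[p[k, "ref"]])
  )
}

#' Correlation and Bland-Altman agreement between paired measurements
#'
#' @param x,y paired measurement vectors (bpm), equal length of at least 3
#'   and non-zero variance.
#' @return list of class `agreement_summary`: `r2` (squared Pearson
#'   correlation), `mean_diff` (mean of `x - y`), `loa_low` / `loa_high`
#'   (mean difference +/- 1.96 sample standard deviations of the
#'   differences, the conventional 95% limits of agreement) and `n_pairs`.
#' @export
agreement <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("agreement needs at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("agreement undefined: zero variance")
  d <- x - y
  md <- mean(d)
  s <- stats::sd(d)
  structure(list(r2 = stats::cor(x, y)^2, mean_diff = md,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 n_pairs = length(x)),
            class = "agreement_summary")
}

#' Score one recording's detections against its ECG reference
#'
#' Produces a one-row summary in the layout of a per-recording results
#' table: beat count, TP/FP/FN, TPR, PPV and the squared correlation of
#' instantaneous heart rate over the paired TP intervals (`NA` when fewer
#' than 3 pairs exist).
#'
#' @param detected a [beat_list()] (or timestamp vector).
#' @param reference an [r_peak_list()] (or timestamp vector).
#' @param tol matching tolerance, seconds (default 0.25).
#' @return data.frame with columns `beats`, `TP`, `FP`, `FN`, `TPR`, `PPV`,
#'   `r2`.
#' @export
evaluate_detection <- function(detected, reference, tol = 0.25) {
  cnt <- match_beats(detected, reference, tol)
  prs <- paired_hr_series(detected, reference, cnt)
  r2 <- if (nrow(prs) >= 3 && stats::sd(prs$detected_bpm) > 0 &&
            stats::sd(prs$reference_bpm) > 0)
    agreement(prs$detected_bpm, prs$reference_bpm)$r2 else NA_real_
  data.frame(beats = cnt$n_ref, TP = cnt$tp, FP = cnt$fp, FN = cnt$fn,
             TPR = if (cnt$n_ref > 0) tpr(cnt) else NA_real_,
             PPV = if (cnt$tp + cnt$fp > 0) ppv(cnt) else NA_real_,
             r2 = r2)
}
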