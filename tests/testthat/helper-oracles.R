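# Independent brute-force oracles used to cross-check the implementation.
# These are written against the documented definitions with plain loops, not
# against the package internals.

# strict three-point local extrema with plateau-first rule, loop version
oracle_extrema <- function(x) {
  n <- length(x)
  ismax <- ismin <- logical(n)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau [i, j]
    if (j < n) {
      if (x[i - 1L] < x[i] && x[j + 1L] < x[i]) ismax[i] <- TRUE
      if (x[i - 1L] > x[i] && x[j + 1L] > x[i]) ismin[i] <- TRUE
    }
    i <- j + 1L
  }
  list(max = ismax, min = ismin)
}

# naive O(n*w) VarWin, heart-rate variant
oracle_varwin_hr <- function(x, fs, span_ms = 250) {
  s <- round(span_ms / 1000 * fs)
  h <- max(1L, floor(s / 2))
  n <- length(x)
  ex <- oracle_extrema(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    rng <- max(x[lo:hi]) - min(x[lo:hi])
    ilo <- max(1L, i - h + 1L); ihi <- min(n, i + h - 1L)
    g <- any(ex$max[ilo:ihi]) && any(ex$min[ilo:ihi])
    out[i] <- rng * g
  }
  out
}

# naive O(n*w) VarWin, beat variant (forward window + deep-minimum suppression)
oracle_varwin_beat <- function(x, fs, span_ms = 250, suppress_ms = span_ms,
                               min_depth_frac = 0.3) {
  s <- round(span_ms / 1000 * fs)
  n <- length(x)
  ex <- oracle_extrema(x)
  lo_v <- min(x)
  deep <- which(ex$min & (x <= lo_v + min_depth_frac * (max(x) - lo_v)))
  ss <- max(1L, round(suppress_ms / 1000 * fs))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(n, i + s)
    rng <- max(x[i:hi]) - min(x[i:hi])
    ilo <- min(n, i + 1L); ihi <- min(n, i + s - 1L)
    g <- ilo <= ihi && any(ex$max[ilo:ihi]) && any(ex$min[ilo:ihi])
    sup <- any(deep >= i - ss & deep <= i - 1L)
    out[i] <- rng * g * !sup
  }
  out
}

# exact maximum-cardinality one-to-one matching by dynamic programming
# (an optimal non-crossing matching always exists for tolerance windows on
# a line, so the DP over sorted lists is globally optimal)
oracle_match_counts <- function(det, ref, tol) {
  nd <- length(det); nr <- length(ref)
  dp <- matrix(0L, nd + 1L, nr + 1L)
  for (i in seq_len(nd)) {
    for (j in seq_len(nr)) {
      best <- max(dp[i, j + 1L], dp[i + 1L, j])
      if (abs(det[i] - ref[j]) <= tol) best <- max(best, dp[i, j] + 1L)
      dp[i + 1L, j + 1L] <- best
    }
  }
  tp <- dp[nd + 1L, nr + 1L]
  c(tp = tp, fp = nd - tp, fn = nr - tp)
}

# quick clean-ish simulated recording for pipeline tests
quick_sim <- function(duration = 60, mean_hr = 70, seed = 42, ...) {
  simulate_recording(sim_config(duration = duration, mean_hr = mean_hr,
                                seed = seed, ...))
}
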