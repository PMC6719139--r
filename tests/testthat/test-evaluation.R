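test_that("tolerance-window matching counts TP/FP/FN correctly", {
  m <- match_beats(1.200, 1.000, 0.250)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  m <- match_beats(1.300, 1.000, 0.250)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 1))
  m <- match_beats(numeric(0), c(1, 2), 0.25)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 0, 2))
  expect_equal(m$n_ref, m$tp + m$fn)
})

test_that("shifted detections plus spurious extras are scored exactly", {
  set.seed(21)
  ref <- sort(runif(100, 0, 100))
  ref <- ref[c(TRUE, diff(ref) > 0.6)]
  det <- sort(c(ref + 0.1, runif(5, 101, 110)))
  m <- match_beats(det, ref, 0.25)
  expect_equal(m$tp, length(ref))
  expect_equal(m$fp, 5)
  expect_equal(m$fn, 0)
  o <- oracle_match_counts(det, ref, 0.25)
  expect_equal(c(m$tp, m$fp, m$fn), unname(o))
})

test_that("matching equals the exhaustive optimal assignment on small instances", {
  set.seed(33)
  for (k in 1:100) {
    nd <- sample(0:12, 1); nr <- sample(0:12, 1)
    det <- sort(runif(nd, 0, 10))
    ref <- sort(runif(nr, 0, 10))
    tol <- runif(1, 0.05, 0.6)
    m <- match_beats(det, ref, tol)
    o <- oracle_match_counts(det, ref, tol)
    expect_equal(c(m$tp, m$fp, m$fn), unname(o))
    expect_equal(m$tp + m$fn, nr)
  }
  # a crossing configuration where nearest-first greedy would drop a match
  m <- match_beats(c(0.25, 0.50), c(0, 0.26), 0.25)
  expect_equal(m$tp, 2)
})

test_that("TPR and PPV reproduce reference worked examples", {
  mk <- function(tp, fp, fn) list(tp = tp, fp = fp, fn = fn)
  expect_lt(abs(tpr(mk(23162, 75, 819)) - 0.9657), 1.5e-4)
  expect_equal(round(ppv(mk(23162, 75, 819)), 4), 0.9968)
  expect_equal(round(tpr(mk(537, 1, 28)), 4), 0.9504)
  expect_equal(round(ppv(mk(501, 11, 38)), 4), 0.9785)
  expect_equal(tpr(mk(5, 0, 0)), 1)
  expect_equal(ppv(mk(7, 0, 0)), 1)
  expect_error(tpr(mk(0, 3, 0)), "undefined")
  expect_error(ppv(mk(0, 0, 3)), "undefined")
})

test_that("rates are invariant to the irrelevant error type", {
  base <- list(tp = 50, fp = 5, fn = 10)
  expect_equal(tpr(base), tpr(list(tp = 50, fp = 99, fn = 10)))
  expect_equal(ppv(base), ppv(list(tp = 50, fp = 5, fn = 99)))
})

test_that("interval pairing drops pairs broken by misses", {
  ref <- c(1, 2, 3, 4, 5)
  det <- c(1.01, 2.01, 4.01, 5.01)       # beat at 3 missed
  m <- match_beats(det, ref, 0.25)
  prs <- paired_hr_series(det, ref, m)
  # pairs: (1,2), (4,5); the two intervals adjacent to the miss are excluded
  expect_equal(nrow(prs), 2)
  expect_equal(prs$reference_bpm, c(60, 60))
  expect_equal(prs$detected_bpm, c(60, 60), tolerance = 1e-9)
  # perfect detection of a 3-beat record
  m2 <- match_beats(ref[1:3], ref[1:3], 0.25)
  prs2 <- paired_hr_series(ref[1:3], ref[1:3], m2)
  expect_equal(nrow(prs2), 2)
  expect_equal(prs2$detected_bpm, prs2$reference_bpm)
  # fewer than 2 TP beats: empty pairing
  expect_equal(nrow(paired_hr_series(1.01, 1, match_beats(1.01, 1, 0.25))), 0)
})

test_that("pair count equals TP minus the number of TP runs", {
  set.seed(8)
  for (k in 1:20) {
    ref <- cumsum(runif(30, 0.6, 1.2))
    drop <- sort(sample(30, 5))
    det <- ref[-drop] + runif(25, -0.05, 0.05)
    m <- match_beats(det, ref, 0.25)
    prs <- paired_hr_series(det, ref, m)
    runs <- sum(diff(c(-10, m$pairs[, "ref"])) > 1)
    expect_equal(nrow(prs), m$tp - runs)
  }
})

test_that("agreement summarises correlation and limits of agreement", {
  x <- seq(1, 50)
  a <- agreement(2 * x + 3, x)
  expect_equal(a$r2, 1)
  expect_equal(a$mean_diff, mean(x + 3))
  b <- agreement(x, x)
  expect_equal(b$r2, 1)
  expect_equal(c(b$mean_diff, b$loa_low, b$loa_high), c(0, 0, 0))
  set.seed(99)
  u <- rnorm(1000)
  v <- 0.9 * u + sqrt(1 - 0.81) * rnorm(1000)
  g <- agreement(u, v)
  expect_gt(g$r2, 0.78); expect_lt(g$r2, 0.84)
  expect_equal(g$r2, agreement(v, u)$r2)
  expect_true(g$loa_low <= g$mean_diff && g$mean_diff <= g$loa_high)
  expect_error(agreement(rep(1, 5), 1:5), "zero variance")
})

test_that("per-recording evaluation mirrors the module calls", {
  sim <- quick_sim(duration = 40, mean_hr = 72, seed = 6)
  res <- detect_recording(sim$recording)
  ev <- evaluate_detection(res$beats, sim$truth$ao_times, 0.25)
  m <- match_beats(res$beats, sim$truth$ao_times, 0.25)
  expect_equal(ev$TP, m$tp)
  expect_equal(ev$TPR, tpr(m))
  expect_equal(ev$PPV, ppv(m))
  expect_true(ev$r2 > 0.8)
})
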