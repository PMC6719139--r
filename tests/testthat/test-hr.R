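fs <- 200

impulse_train <- function(hz, dur_s, fs) {
  x <- rep(0, round(dur_s * fs))
  x[round(seq(1, length(x), by = fs / hz))] <- 1
  uniform_signal(x, fs)
}

test_that("autocorrelation recovers the rate of periodic trains", {
  e1 <- hr_from_window(impulse_train(1, 10, fs))
  expect_equal(e1$hr_bpm, 60, tolerance = 1)
  expect_equal(e1$hr_bpm, 60 / e1$btb_s, tolerance = 1e-9)

  e2 <- hr_from_window(impulse_train(2.2, 10, fs))
  expect_equal(e2$hr_bpm, 132, tolerance = 2)

  # harmonic disambiguation: the fundamental lag is chosen, not a subharmonic
  expect_lt(e2$btb_s, 0.5)
})

test_that("white noise rarely produces an estimate", {
  absent <- 0
  for (s in 1:100) {
    set.seed(s)
    e <- hr_from_window(uniform_signal(abs(rnorm(2000)), fs))
    if (is.na(e$hr_bpm)) absent <- absent + 1
  }
  expect_gte(absent, 95)
})

test_that("degenerate inputs give absent estimates or errors", {
  expect_true(is.na(hr_from_window(uniform_signal(rep(0, 2000), fs))$hr_bpm))
  expect_error(hr_from_window(impulse_train(1, 10, fs), bounds = c(200, 30)),
               "inverted")
  # 2 s window cannot see a 40 bpm rhythm (lag capped at half the window)
  x <- rep(0, 400); x[c(1, 301)] <- 1
  expect_true(is.na(hr_from_window(uniform_signal(x, fs))$hr_bpm))
})

test_that("window fusion weights inversely to window size", {
  mk <- function(n, hr) structure(list(window_s = n, axis = "aZ",
                                       hr_bpm = hr, btb_s = 60 / hr,
                                       confidence = 1),
                                  class = "window_estimate")
  expect_equal(fuse_windows(list(mk(2, 60), mk(5, 60), mk(10, 60))), 60)
  expect_equal(fuse_windows(list(mk(2, 60), mk(10, 70))),
               (60 / 2 + 70 / 10) / (1 / 2 + 1 / 10))
  expect_equal(fuse_windows(list(mk(2, NA), mk(7, 85), mk(10, NA))), 85)
  expect_true(is.na(fuse_windows(list(mk(2, NA), mk(10, NA)))))
  bad <- list(mk(2, 60), structure(list(window_s = 3, axis = "gX",
                                        hr_bpm = 60, btb_s = 1, confidence = 1),
                                   class = "window_estimate"))
  expect_error(fuse_windows(bad), "mixed axes")
})

test_that("axis consolidation follows the dual-measurement decision table", {
  # agreement within 10 bpm: average
  m <- consolidate_axes(70, 72, NA, 10)
  expect_equal(m$hr_bpm, 71)
  expect_equal(m$source, "both-agree")
  # disagreement: previous measurement arbitrates
  m <- consolidate_axes(70, 90, 68, 10)
  expect_equal(m$hr_bpm, 70); expect_equal(m$source, "scg-selected")
  m <- consolidate_axes(70, 90, 88, 10)
  expect_equal(m$hr_bpm, 90); expect_equal(m$source, "gcg-selected")
  # disagreement without a previous reference: SCG wins
  m <- consolidate_axes(70, 90, NA, 10)
  expect_equal(m$hr_bpm, 70); expect_equal(m$source, "scg-selected")
  # single-axis passthrough
  expect_equal(consolidate_axes(65, NA, NA, 10)$source, "scg-selected")
  expect_equal(consolidate_axes(NA, 65, 80, 10)$hr_bpm, 65)
  # nothing measured: carry the previous value forward, else absent
  m <- consolidate_axes(NA, NA, 77, 10)
  expect_equal(m$hr_bpm, 77); expect_equal(m$source, "carry-forward")
  expect_true(is.na(consolidate_axes(NA, NA, NA, 10)$hr_bpm))
})

test_that("consolidation identities hold over random inputs", {
  set.seed(5)
  for (k in 1:50) {
    h <- runif(1, 40, 150)
    p <- runif(1, 40, 150)
    # exact agreement returns the shared value regardless of prev
    expect_equal(consolidate_axes(h, h, p, 10)$hr_bpm, h)
    # equidistant disagreement always resolves to SCG
    d <- runif(1, 11, 30)
    m <- consolidate_axes(p - d, p + d, p, 10)
    expect_equal(m$hr_bpm, p - d)
    expect_equal(m$source, "scg-selected")
  }
})
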