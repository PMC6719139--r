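fs <- 200

test_that("VarWin is zero on constant and monotone inputs", {
  for (v in list(varwin_hr, varwin_beat)) {
    expect_true(all(v(uniform_signal(rep(3, 500), fs))$values == 0))
    expect_true(all(v(uniform_signal(seq_len(500) * 0.1, fs))$values == 0))
  }
})

test_that("a single biphasic pulse yields one contiguous enhancement region", {
  t <- (0:799) / fs
  x <- exp(-(t - 2)^2 / (2 * 0.02^2)) - exp(-(t - 2.1)^2 / (2 * 0.02^2))
  enh <- varwin_hr(uniform_signal(x, fs), 250)
  nz <- which(enh$values > 1e-9)
  expect_gt(length(nz), 0)
  expect_equal(nz, seq(min(nz), max(nz)))    # contiguous
  # the top of the enhancement covers the span between the pulse extrema
  peak_idx <- which(enh$values == max(enh$values))
  j1 <- which.max(x); j2 <- which.min(x)
  expect_gt(max(peak_idx), j1 - 0.25 * fs)
  expect_true(any(peak_idx >= j1 & peak_idx <= j2) || min(peak_idx) < j1)
  expect_equal(max(enh$values), max(x) - min(x), tolerance = 1e-9)
})

test_that("fast VarWin equals the naive sliding-window oracle bit-for-bit", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(800)
    expect_identical(varwin_hr(uniform_signal(x, fs), 250)$values,
                     oracle_varwin_hr(x, fs, 250))
    expect_identical(varwin_beat(uniform_signal(x, fs), 250)$values,
                     oracle_varwin_beat(x, fs, 250))
    # non-default spans and suppression
    expect_identical(varwin_hr(uniform_signal(x, fs), 120)$values,
                     oracle_varwin_hr(x, fs, 120))
    expect_identical(varwin_beat(uniform_signal(x, fs), 120, 60)$values,
                     oracle_varwin_beat(x, fs, 120, 60))
  }
})

test_that("VarWin is scale-covariant and offset-invariant", {
  for (s in 1:5) {
    set.seed(100 + s)
    x <- cumsum(rnorm(600))
    base_hr <- varwin_hr(uniform_signal(x, fs))$values
    base_bt <- varwin_beat(uniform_signal(x, fs))$values
    c0 <- runif(1, 0.5, 5)
    k <- runif(1, -10, 10)
    expect_equal(varwin_hr(uniform_signal(c0 * x + k, fs))$values,
                 c0 * base_hr, tolerance = 1e-12)
    expect_equal(varwin_beat(uniform_signal(c0 * x + k, fs))$values,
                 c0 * base_bt, tolerance = 1e-12)
  }
})

test_that("output is zero wherever the input is locally monotone over the span", {
  set.seed(9)
  # piecewise long ramps: interior of each ramp has no extremum in span
  x <- c(seq(0, 1, length.out = 200), seq(1, -1, length.out = 300),
         seq(-1, 0.5, length.out = 300))
  enh <- varwin_hr(uniform_signal(x, fs), 250)
  s <- round(0.25 * fs)
  mono_idx <- 100           # deep inside the first ramp
  expect_identical(enh$values[mono_idx], 0)
  expect_identical(enh$values[350], 0)   # inside second ramp
})

test_that("beat variant amplifies the AO lead-in over the AC complex", {
  t <- (0:399) / fs
  g <- function(mu, A, s = 0.015) A * exp(-(t - mu)^2 / (2 * s^2))
  # equal-amplitude S1 (AO 1.0, IC 1.1) and S2 (AC 1.32, MO 1.40) complexes
  x <- g(1.0, 1) + g(1.1, -1) + g(1.32, 1) + g(1.40, -1)
  enh <- varwin_beat(uniform_signal(x, fs), 250)
  tt <- signal_times(enh)
  ao_lead <- max(enh$values[tt > 0.75 & tt <= 1.0])
  ac_lead <- max(enh$values[tt > 1.1 & tt <= 1.32])
  expect_gt(ao_lead, ac_lead)
  expect_gt(ao_lead, 1.9)      # full AO-IC swing
  expect_lt(ac_lead, 0.1)      # suppressed after the deep IC minimum
})

test_that("forward-looking window rises ahead of the oscillation", {
  t <- (0:399) / fs
  x <- exp(-(t - 1.5)^2 / (2 * 0.02^2)) - exp(-(t - 1.6)^2 / (2 * 0.02^2))
  enh <- varwin_beat(uniform_signal(x, fs), 250)
  j1 <- which.max(x)
  # all enhancement at/above half maximum happens at or before the peak
  high <- which(enh$values > 0.5 * max(enh$values))
  expect_lte(max(high), j1 + 1)
})

test_that("deep-minimum suppression ignores shallow noise minima", {
  set.seed(3)
  t <- (0:999) / fs
  x <- exp(-(t - 2)^2 / (2 * 0.02^2)) - exp(-(t - 2.1)^2 / (2 * 0.02^2)) +
       0.02 * rnorm(1000)
  enh <- varwin_beat(uniform_signal(x, fs), 250)
  # enhancement ahead of the pulse survives (noise minima do not suppress it)
  lead <- signal_times(enh) > 1.8 & signal_times(enh) < 2.0
  expect_gt(max(enh$values[lead]), 1)
})

test_that("span shorter than 3 samples or longer than the signal errors", {
  expect_error(varwin_hr(uniform_signal(rnorm(100), fs), 5), "span")
  expect_error(varwin_hr(uniform_signal(rnorm(40), fs), 250), "longer")
})
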