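test_that("deterministic beat times follow the configured rate exactly", {
  cfg <- sim_config(duration = 10, mean_hr = 60, hrv_sd = 0, resp_mod = 0,
                    pep_delay = 0.1, seed = 1)
  gt <- generate_beat_times(cfg)
  expect_equal(gt$r_times, 0:9)
  expect_equal(gt$ao_times - gt$r_times, rep(0.1, 10))
  expect_equal(gt$instantaneous_hr, rep(60, 9))
})

test_that("recovery trend decays between the configured rates", {
  cfg <- sim_config(duration = 300, hrv_sd = 0, resp_mod = 0,
                    hr_trend = list(start = 140, end = 70, tau = 60), seed = 1)
  gt <- generate_beat_times(cfg)
  expect_equal(gt$rr_s[1], 60 / 140, tolerance = 0.01)
  expect_equal(tail(gt$rr_s, 1), 60 / 70, tolerance = 0.02)
  expect_true(all(diff(gt$rr_s) > -1e-9))
})

test_that("beat-to-beat variability magnitude is recovered from the draws", {
  cfg <- sim_config(duration = 450, mean_hr = 70, hrv_sd = 0.05,
                    resp_mod = 0, seed = 12)
  gt <- generate_beat_times(cfg)
  expect_gt(length(gt$rr_s), 450)
  cv <- sd(gt$rr_s / mean(gt$rr_s))
  expect_lt(abs(cv - 0.05), 0.007)
})

test_that("invalid simulation parameters error", {
  expect_error(sim_config(duration = -5), "duration")
  expect_error(generate_beat_times(sim_config(mean_hr = 70, hrv_sd = 30,
                                              seed = 4)),
               "non-positive RR")
})

test_that("identical seed and config reproduce the recording bit-for-bit", {
  a <- simulate_recording(sim_config(duration = 10, seed = 99))
  b <- simulate_recording(sim_config(duration = 10, seed = 99))
  expect_identical(a$recording$timestamps, b$recording$timestamps)
  expect_identical(a$recording$channels, b$recording$channels)
  expect_identical(a$truth$r_times, b$truth$r_times)
})

test_that("noise-free morphology puts the aZ peak at the AO time", {
  cfg <- sim_config(duration = 4, mean_hr = 30, hrv_sd = 0, resp_mod = 0,
                    noise_snr_db = Inf, wander_rel = 0, jitter_sd = 0,
                    seed = 2)
  gt <- generate_beat_times(cfg)
  rec <- synthesize_recording(gt, cfg)
  t <- rec$timestamps
  for (a in gt$ao_times) {
    reg <- which(t > a - 0.15 & t < a + 0.15)
    expect_lt(abs(t[reg[which.max(abs(rec$channels$aZ[reg]))]] - a), 0.02)
  }
  # the gyro S2 complex is attenuated relative to the accelerometer S2
  s2_win <- t > gt$ao_times[1] + 0.25 & t < gt$ao_times[1] + 0.55
  s1_win <- t > gt$ao_times[1] - 0.1 & t < gt$ao_times[1] + 0.2
  rel_aZ <- max(abs(rec$channels$aZ[s2_win])) / max(abs(rec$channels$aZ[s1_win]))
  rel_gX <- max(abs(rec$channels$gX[s2_win])) / max(abs(rec$channels$gX[s1_win]))
  expect_gt(rel_aZ, rel_gX * 2)
})

test_that("clean ECG channel is recovered beat-for-beat by the reference detector", {
  sim <- quick_sim(duration = 30, mean_hr = 65, seed = 31,
                   noise_snr_db = Inf, jitter_sd = 0)
  pk <- pan_tompkins(resample_uniform(sim$recording, "ecg", 200))
  for (r in sim$truth$r_times[sim$truth$r_times >= 0.5])
    expect_lt(min(abs(pk$timestamps - r)), 0.02)
})

test_that("baseline wander lies below the high-pass cutoff", {
  sim <- quick_sim(duration = 20, mean_hr = 70, seed = 14, noise_snr_db = Inf)
  sig <- resample_uniform(sim$recording, "aZ", 200)
  hp <- highpass_brickwall(sig, 0.4)
  low_energy <- function(v, fs) {
    X <- Mod(fft(v - mean(v)))^2
    f <- pmin(0:(length(v) - 1), length(v) - (0:(length(v) - 1))) * fs / length(v)
    sum(X[f < 0.4 & f > 0])
  }
  expect_lt(low_energy(hp$values, 200), 0.01 * low_energy(sig$values, 200))
})

test_that("ground truth and recordings serialise to plain text", {
  sim <- quick_sim(duration = 5, seed = 8)
  rp <- withr::local_tempfile(fileext = ".txt")
  ap <- withr::local_tempfile(fileext = ".txt")
  write_ground_truth(sim$truth, rp, ap)
  expect_equal(read_beat_annotations(ap), sim$truth$ao_times, tolerance = 1e-6)
  expect_equal(read_beat_annotations(rp), sim$truth$r_times, tolerance = 1e-6)
})
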