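test_that("bandpass filter passes the sEMG band and rejects drift", {
  fs <- 2000
  t <- seq(0, 4, by = 1 / fs)[-1]
  steady <- 2001:6000  # interior segment clear of filter edge transients
  rms <- function(x) sqrt(mean(x^2))

  in_band <- emg_signal(matrix(sin(2 * pi * 100 * t), 1), fs)
  out <- bandpass_filter(in_band)
  expect_gt(rms(out$data[1, steady]) / rms(in_band$data[1, steady]), 0.9)
  expect_lte(rms(out$data[1, steady]) / rms(in_band$data[1, steady]), 1.0)

  drift <- emg_signal(matrix(sin(2 * pi * 2 * t), 1), fs)
  out <- bandpass_filter(drift)
  expect_lt(rms(out$data[1, steady]) / rms(drift$data[1, steady]), 0.1)

  zeros <- emg_signal(matrix(0, 3, 1000), fs)
  expect_true(all(bandpass_filter(zeros)$data == 0))
})

test_that("bandpass filter validates its cutoffs and preserves shape", {
  x <- emg_signal(matrix(rnorm(2 * 2000), 2), fs = 800)
  expect_error(bandpass_filter(x, high_hz = 450), "Nyquist")
  expect_error(bandpass_filter(x, low_hz = 0, high_hz = 100), "low_hz")
  y <- bandpass_filter(x, low_hz = 10, high_hz = 350)
  expect_equal(dim(y$data), dim(x$data))
  expect_identical(y$channel_names, x$channel_names)
  # causal mode differs from zero-phase but keeps dimensions
  yc <- bandpass_filter(x, low_hz = 10, high_hz = 350, zero_phase = FALSE)
  expect_equal(dim(yc$data), dim(x$data))
  expect_false(identical(y$data, yc$data))
})

test_that("window segmentation matches brute-force enumeration", {
  cfg <- windowing_config()
  expect_identical(cfg$window_samples, 300L)
  expect_identical(cfg$step_samples, 50L)

  w <- segment_windows(300, cfg)
  expect_equal(unname(w), cbind(0L, 300L))

  w <- segment_windows(1000, cfg)
  # brute force: every 50-multiple start whose window fits
  starts <- Filter(function(s) s + 300 <= 1000, seq(0, 1000, by = 50))
  expect_equal(nrow(w), 15L)
  expect_equal(w[, "start"], as.integer(starts))
  expect_equal(unname(w[15, ]), c(700L, 1000L))

  expect_error(segment_windows(299, cfg), "299")

  for (n in sample(300:5000, 25)) {
    w <- segment_windows(n, cfg)
    expect_equal(nrow(w), floor((n - 300) / 50) + 1)
    expect_true(all(w[, "end"] - w[, "start"] == 300L))
    expect_true(all(w[, "end"] <= n))
  }
})

test_that("windowing configuration rejects inconsistent parameters", {
  expect_error(windowing_config(window_ms = 150.3, fs = 2000), "whole sample")
  expect_error(windowing_config(window_ms = 25, step_ms = 150), "step")
  cfg <- windowing_config(window_ms = 100, step_ms = 20, fs = 1000)
  expect_identical(cfg$window_samples, 100L)
  expect_identical(cfg$step_samples, 20L)
})

test_that("mav matches its definition", {
  expect_equal(mav(c(1, -1, 2, -2)), 1.5)
  expect_equal(mav(rep(0, 10)), 0)
  expect_error(mav(numeric(0)), "nonempty")
  set.seed(1)
  w <- rnorm(300)
  brute <- sum(abs(w)) / 300
  expect_equal(mav(w), brute, tolerance = 1e-12)
})

test_that("feature extraction aligns MAV windows with trailing angles", {
  fs <- 2000
  n <- 1000
  cfg <- windowing_config(fs = fs)
  emg <- emg_signal(matrix(1, 1, n), fs)
  ang <- angle_signal(matrix(seq_len(n), 1), fs)  # angle = sample index
  pair <- extract_training_pair(emg, ang, cfg)
  expect_equal(pair$M, 15L)
  expect_true(all(pair$Z == 1))
  # "last value" of window k is the sample at its trailing edge
  expect_equal(as.numeric(pair$X), seq(300, 1000, by = 50))

  const <- angle_signal(matrix(c(30, 45), 2, n), fs)
  emg2 <- emg_signal(matrix(rnorm(2 * n), 2), fs)
  pair2 <- extract_training_pair(emg2, const, cfg)
  expect_true(all(pair2$X == c(30, 45)))

  # MAV is invariant to a sign flip of the EMG
  flipped <- emg_signal(-emg2$data, fs)
  expect_equal(extract_training_pair(flipped, const, cfg)$Z, pair2$Z)
})

test_that("misaligned or short inputs are rejected with both lengths", {
  fs <- 2000
  emg <- emg_signal(matrix(rnorm(1000), 1), fs)
  ang <- angle_signal(matrix(rnorm(900), 1), fs)
  expect_error(extract_training_pair(emg, ang), "1000.*900")
  ang2 <- angle_signal(matrix(rnorm(1000), 1), fs = 1000)
  expect_error(extract_training_pair(emg, ang2), "fs")
})

test_that("a one-minute session yields the closed-form window count", {
  s <- generate_session(duration_s = 60, seed = 1)
  pair <- extract_training_pair(s$emg, s$angles)
  expect_equal(pair$M, floor((120000 - 300) / 50) + 1)  # 2395
  expect_equal(ncol(pair$Z), pair$M)
  expect_equal(ncol(pair$X), pair$M)
})

test_that("training pairs from several sessions concatenate per session", {
  p1 <- quick_pair(1, duration_s = 4)
  p2 <- quick_pair(2, duration_s = 4)
  both <- bind_training_pairs(p1, p2)
  expect_equal(both$M, p1$M + p2$M)
  expect_equal(both$Z[, seq_len(p1$M)], p1$Z)
  expect_equal(both$X[, p1$M + seq_len(p2$M)], p2$X)
})
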