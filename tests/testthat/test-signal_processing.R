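test_that("process_emg recovers the rectified-mean envelope of a sinusoid", {
  fs <- 2000
  t <- (0:(6 * fs - 1)) / fs
  A <- 0.8
  x <- A * sin(2 * pi * 100 * t)
  env <- process_emg(x, fs)
  interior <- env[(2 * fs):(4 * fs)]
  # mean of a rectified sinusoid is 2A/pi; the 6 Hz low-pass keeps that mean
  expect_equal(mean(interior), 2 * A / pi, tolerance = 0.02)
  expect_true(all(env >= 0))
  # sign-flip invariance (rectification)
  expect_equal(process_emg(-x, fs), env, tolerance = 1e-10)
  # all-zero input stays zero; DC is removed by the band-pass
  expect_equal(process_emg(rep(0, 4000), fs), rep(0, 4000))
  dc <- process_emg(rep(1, 4 * fs), fs)
  expect_lt(max(abs(dc[fs:(3 * fs)])), 1e-6)
  expect_error(process_emg(x, 1000), "band edge")
  expect_error(process_emg(c(1, NA, 2), fs), "NA")
})

test_that("low-pass filters match the closed-form Butterworth response", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  # constant signal is untouched (DC gain exactly 1)
  const <- lowpass_grf(gait_ts(t, list(x = rep(3.7, length(t)))))
  expect_equal(const$channels$x, rep(3.7, length(t)), tolerance = 1e-9)
  # 50 Hz is attenuated at least 40 dB by the 6 Hz order-4 zero-phase filter
  s50 <- gait_ts(t, list(x = sin(2 * pi * 50 * t)))
  y50 <- lowpass_grf(s50)$channels$x
  expect_lt(max(abs(y50[1000:4000])), 1e-2)
  # closed-form analog response, doubled margin for bilinear warping
  expect_lt(max(abs(y50[1000:4000])), 2 * butter_zp_gain(50, 6, 4))
  # 0.5 Hz passes within 1% (both filter orders)
  s05 <- gait_ts(t, list(x = sin(2 * pi * 0.5 * t)))
  expect_equal(max(abs(lowpass_grf(s05)$channels$x[1000:4000])), 1,
               tolerance = 0.01)
  expect_equal(max(abs(lowpass_kinematics(s05)$channels$x[1000:4000])), 1,
               tolerance = 0.01)
  expect_error(lowpass_grf(gait_ts(0:10, list(x = rep(0, 11)), rate = 1)),
               "cutoff")
})

test_that("filtering is zero-phase (no lag on a band-interior sinusoid)", {
  fs <- 1000
  t <- (0:4999) / fs
  x <- sin(2 * pi * 2 * t)
  y <- filtfilt_zp(butter_design(4, 6, fs, "low"), x)
  cc <- stats::ccf(y[500:4500], x[500:4500], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("segment_steps finds threshold-crossing stance windows", {
  rate <- 1000
  pulse <- c(rep(0, 200), seq(0, 700, length.out = 100), rep(700, 300),
             seq(700, 0, length.out = 100), rep(0, 200))
  w <- segment_steps(pulse, rate, threshold = 20)
  expect_equal(nrow(w), 1L)
  expect_true(all(pulse[w$onset[1]:(w$offset[1] - 1)] > 20))
  expect_true(pulse[w$onset[1] - 1] <= 20 && pulse[w$offset[1]] <= 20)

  expect_equal(nrow(segment_steps(rep(0, 1000), rate, 20)), 0L)

  two <- c(pulse, pulse)
  w2 <- segment_steps(two, rate, 20)
  expect_equal(nrow(w2), 2L)
  expect_lt(w2$offset[1], w2$onset[2])

  # time-shift equivariance
  shift <- 150L
  w3 <- segment_steps(c(rep(0, shift), pulse), rate, 20)
  expect_equal(w3$onset, w$onset + shift)
  expect_equal(w3$offset, w$offset + shift)

  # short blips below the minimum stance duration are discarded
  blip <- c(rep(0, 100), rep(500, 50), rep(0, 100))
  expect_equal(nrow(segment_steps(blip, rate, 20, min_stance = 0.3)), 0L)
  expect_error(segment_steps(pulse, rate, threshold = 0), "threshold")
})

test_that("stance_mean and resample_stance agree with direct computation", {
  w <- list(onset = 11L, offset = 31L, duration = 0.02)
  x <- rep(0.2, 50)
  expect_equal(stance_mean(x, w), 0.2)
  ramp <- seq(0, 1, length.out = 100)
  expect_equal(stance_mean(ramp, list(onset = 1L, offset = 101L)), 0.5)
  expect_error(stance_mean(x, list(onset = 40L, offset = 60L)), "outside")
  expect_error(stance_mean(x, list(onset = 10L, offset = 10L)), "empty")

  expect_equal(resample_stance(rep(2.5, 40), list(onset = 5L, offset = 35L), 11),
               rep(2.5, 11))
  lin <- seq(10, 20, length.out = 50)
  rs <- resample_stance(lin, list(onset = 1L, offset = 51L), 101)
  expect_equal(rs[1], 10)
  expect_equal(rs[101], 20)
  expect_equal(resample_stance(lin, list(onset = 3L, offset = 10L), 2),
               c(lin[3], lin[9]))
  expect_error(resample_stance(lin, list(onset = 1L, offset = 51L), 1), ">= 2")

  # Riemann consistency: the 101-point resampled mean tracks the raw mean
  set.seed(3)
  y <- cumsum(rnorm(400)) / 10 + 5
  wq <- list(onset = 21L, offset = 381L)
  expect_equal(mean(resample_stance(y, wq, 101)), stance_mean(y, wq),
               tolerance = 1e-3)
})

test_that("apply_emg_delay shifts by round(delay * rate) with first-value pad", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(apply_emg_delay(x, 1000, 0.002), c(1, 1, 1, 2, 3, 4))
  expect_equal(apply_emg_delay(x, 1000, 0), x)
  x2 <- seq_len(100)
  expect_equal(apply_emg_delay(x2, 1000, 0.040), c(rep(1, 40), 1:60))
  expect_equal(apply_emg_delay(x2, 500, 0.040), c(rep(1, 20), 1:80))
  expect_error(apply_emg_delay(x, 1000, -0.01), ">= 0")
})
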