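test_that("motion classification thresholds window means with ties going low", {
  # all-zero change: every window low
  cum0 <- rep(0, 300)
  m0 <- classify_motion(cum0, sample_rate_hz = 1, window_s = 60)
  expect_true(all(m0$state == "low"))

  # three 60-sample windows with increments 0, 10T, 0
  thr <- 2
  increments <- c(rep(0, 60), rep(10 * thr, 60), rep(0, 60))
  cum <- cumsum(increments)
  m <- classify_motion(cum, sample_rate_hz = 1, window_s = 60,
                       threshold = thr)
  expect_equal(m$state, c("low", "high", "low"))

  # exactly at the threshold -> low
  increments2 <- rep(thr, 60)
  m2 <- classify_motion(cumsum(increments2), 1, 60, threshold = thr)
  expect_equal(m2$state, "low")

  # shorter than one window: a single window covers all samples
  m3 <- classify_motion(cumsum(rep(1, 10)), 1, 60, threshold = 0)
  expect_equal(nrow(m3), 1)
  expect_length(attr(m3, "sample_state"), 10)
})

test_that("adaptive low-pass keeps the passband, attenuates artifact band, preserves length", {
  fs <- 64
  t <- seq(0, 20, by = 1 / fs)[-1]
  tone <- sin(2 * pi * 0.5 * t)
  states <- structure(data.frame(), sample_state = rep("low", length(t)))
  band_power <- function(x, f0, width = 0.2) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            taper = 0)
    sum(sp$spec[abs(sp$freq - f0) < width])
  }
  y <- adaptive_lowpass(tone, states, 4, 2.5, fs)
  expect_length(y, length(tone))
  mid <- seq(2 * fs, length(t) - 2 * fs)
  amp_ratio <- max(abs(y[mid])) / max(abs(tone[mid]))
  expect_lt(abs(amp_ratio - 1), 0.05)

  # 30 Hz interference attenuated by >= 20 dB (FFT band-power oracle)
  noisy <- tone + sin(2 * pi * 30 * t)
  y2 <- adaptive_lowpass(noisy, states, 4, 4, fs)
  att_db <- 10 * log10(band_power(noisy, 30) / band_power(y2, 30))
  expect_gt(att_db, 20)

  # all-low-motion output equals the single-pass low-motion filter
  mixed_states <- structure(data.frame(),
                            sample_state = rep("low", length(t)))
  expect_identical(adaptive_lowpass(noisy, mixed_states, 4, 2, fs),
                   adaptive_lowpass(noisy, mixed_states, 4, 4, fs))

  expect_error(adaptive_lowpass(tone, states, 2, 4, fs), "cutoffs")
  expect_error(adaptive_lowpass(tone, states, 40, 2, fs), "cutoffs")
})

test_that("smoothing is a centered mean with shrunken edges", {
  expect_identical(smooth_ppg(c(4, 9, 2), 1), c(4, 9, 2))
  expect_equal(smooth_ppg(rep(7, 10), 5), rep(7, 10))
  expect_equal(smooth_ppg(c(0, 3, 0), 3), c(1.5, 1, 1.5))
  expect_error(smooth_ppg(1:10, 4), "odd")
  set.seed(4)
  x <- rnorm(50)
  s <- smooth_ppg(x, 7)
  expect_equal(s[10], mean(x[7:13]))
})

test_that("beat detection recovers constructed pulse trains and fails flat signals", {
  r <- quiet_recording()
  b <- detect_beats(r$ppg, r$sample_rate_hz)
  expect_true(b$success)
  n_min <- length(r$ppg) / r$sample_rate_hz / 60
  expect_equal(length(b$times) / n_min, 60, tolerance = 0.02)

  # 75 bpm with mild noise: recovered rate within +/-2 bpm
  cfg <- sim_config(n_subjects = 1, duration_min = 3, sample_rate_hz = 32,
                    base_bpm = 75, hr_slope_per_hour = 0,
                    subject_bpm_sd = 0, motion_artifact_gain = 0,
                    seed = 12)
  r75 <- generate_cohort(cfg)$recordings[[1]]
  cleaned <- smooth_ppg(
    adaptive_lowpass(r75$ppg,
                     structure(data.frame(),
                               sample_state = rep("low", length(r75$ppg))),
                     4, 2.5, 32), 9)
  b75 <- detect_beats(cleaned, 32)
  true_bpm <- 60 / mean(diff(r75$true_beats))
  expect_lt(abs(60 / mean(diff(b75$times)) - true_bpm), 2)

  flat <- detect_beats(rep(5, 32 * 20), 32)
  expect_false(flat$success)
  expect_length(flat$times, 0)
  expect_error(detect_beats(rep(5, 10), 32), "10 s")
})

test_that("beat features satisfy the ibi/bpm/RMSSD identities", {
  f <- beat_features(rep(1000, 10))
  expect_equal(f$bpm, 60)
  expect_equal(f$RMSSD, 0)
  f2 <- beat_features(c(800, 1000))
  expect_equal(f2$RMSSD, 200)
  expect_equal(f2$ibi, 900)
  f3 <- beat_features(rep(750, 5))
  expect_equal(f3$bpm, 80)
  expect_false(beat_features(1000)$success)
  # bpm * ibi = 60000 and RMSSD = 0 iff constant IBIs
  set.seed(5)
  for (i in 1:10) {
    ibis <- 800 + round(rnorm(sample(2:30, 1), 0, 50))
    f <- beat_features(ibis)
    expect_equal(f$bpm * f$ibi, 60000, tolerance = 1e-9)
    expect_equal(f$RMSSD == 0, all(diff(ibis) == 0))
  }
})

test_that("breathing rate is recovered from the IBI modulation spectrum", {
  cfg <- sim_config(n_subjects = 1, duration_min = 4, sample_rate_hz = 32,
                    base_bpm = 78, rr_sd_ms = 40,
                    breathing_rate_hz = 0.25, motion_artifact_gain = 0,
                    hr_slope_per_hour = 0, subject_bpm_sd = 0, seed = 8)
  r <- generate_cohort(cfg)$recordings[[1]]
  mf <- ppg_minute_features(r)
  expect_true(all(mf$success))
  expect_lt(abs(median(mf$breathingrate) - 0.25), 0.05)
})

test_that("failed minutes are imputed from the last success, with cold-start defaults", {
  ok <- function(bpm) data.frame(ibi = 60000 / bpm, bpm = bpm,
                                 breathingrate = 0.2, RMSSD = 40,
                                 success = TRUE)
  fail <- data.frame(ibi = NA_real_, bpm = NA_real_,
                     breathingrate = NA_real_, RMSSD = NA_real_,
                     success = FALSE)
  df <- rbind(ok(78), fail, fail)
  df$minute_index <- 1:3
  out <- impute_failures(df)
  expect_equal(out$bpm, c(78, 78, 78))
  expect_equal(out$RMSSD, c(40, 40, 40))

  # no failures: unchanged
  df2 <- rbind(ok(70), ok(75))
  df2$minute_index <- 1:2
  expect_equal(suppressMessages(impute_failures(df2))$bpm, c(70, 75))

  # cold start: first minute failed
  df3 <- rbind(fail, ok(70))
  df3$minute_index <- 1:2
  expect_message(out3 <- impute_failures(df3), "cold-start")
  expect_equal(out3$bpm, c(78, 70))
  expect_equal(out3$ibi[1], 772)
  expect_equal(out3$breathingrate[1], 0.22)
  expect_equal(out3$RMSSD[1], 75.2)
})

test_that("end-to-end HR recovery stays within 3 bpm across the rate grid with motion artifacts", {
  expect_true(all(hr_grid_mae() < 3))
})

test_that("pipeline bpm agrees with an independent autocorrelation HR estimate on clean PPG", {
  # non-gating agreement check against an oracle that never shares code
  # with the peak detector: the lag maximizing the autocorrelation of the
  # clean PPG within the physiological range
  r <- quiet_recording()
  fs <- r$sample_rate_hz
  ac <- stats::acf(r$ppg, lag.max = fs * 2, plot = FALSE)$acf[-1]
  lags <- seq_along(ac) / fs
  valid <- lags >= 60 / 180 & lags <= 60 / 40
  oracle_bpm <- 60 / lags[valid][which.max(ac[valid])]
  mf <- ppg_minute_features(r)
  expect_lt(abs(mean(mf$bpm) - oracle_bpm), 2)
})
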