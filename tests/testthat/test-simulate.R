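test_that("identical seeds reproduce the cohort byte-for-byte, different seeds differ", {
  cfg <- sim_config(n_subjects = 2, duration_min = 3, sample_rate_hz = 16,
                    seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_subjects = 2, duration_min = 3, sample_rate_hz = 16,
                     seed = 43)
  c <- generate_cohort(cfg2)
  expect_false(identical(a$recordings[[1]]$ppg, c$recordings[[1]]$ppg))
})

test_that("conductance and resistance are exact reciprocals at every sample", {
  for (r in small_cohort()$recordings) {
    expect_true(all(abs(r$gsr_conductance * r$gsr_resistance - 1000) < 1e-9))
    expect_true(all(r$gsr_conductance > 0))
  }
})

test_that("recording shape matches the configuration", {
  co <- small_cohort()
  expect_equal(nrow(co$profiles), 3)
  durations <- vapply(co$recordings,
                      function(r) length(r$ppg) / r$sample_rate_hz / 60,
                      numeric(1))
  expect_equal(unname(durations), c(12, 10, 10))
  r <- co$recordings[[1]]
  n <- length(r$ppg)
  for (ch in list(r$timestamp, r$gsr_conductance, r$gsr_resistance,
                  r$temperature, r$pressure))
    expect_length(ch, n)
  expect_equal(dim(r$accel), c(n, 3))
  expect_true(all(diff(r$timestamp) > 0))
  # last drink precedes the first sample
  expect_true(all(co$profiles$last_drink_time <=
                  vapply(co$recordings, function(r) r$timestamp[1],
                         numeric(1))))
})

test_that("config validation rejects degenerate inputs", {
  expect_error(sim_config(n_subjects = 1, duration_min = 1),
               "2 min")
  expect_error(sim_config(n_subjects = 1, duration_min = -5), "positive")
  expect_error(sim_config(activity_transition = matrix(1, 2, 2)),
               "row-stochastic")
  expect_error(sim_config(sample_rate_hz = 2), "8 Hz")
})

test_that("zero-variance RR at 60 bpm gives an exactly 1-second beat period", {
  r <- quiet_recording()
  expect_true(all(abs(diff(r$true_beats) - 1) < 1e-9))
  beats <- detect_beats(smooth_ppg(r$ppg, 9), r$sample_rate_hz)
  expect_true(beats$success)
  expect_true(all(abs(diff(beats$times) - 1) < 1 / r$sample_rate_hz))
})

test_that("with no motion artifact the PPG spectrum peaks at base_bpm/60 Hz", {
  r <- quiet_recording()
  x <- r$ppg - mean(r$ppg)
  sp <- stats::spec.pgram(stats::ts(x, frequency = r$sample_rate_hz),
                          plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)]
  bin <- diff(sp$freq[1:2])
  expect_lt(abs(f_peak - 1), bin + 1e-12)
})

test_that("per-minute GSR mean correlates with hours-since-drinking in the configured sign", {
  co <- small_cohort()   # default negative tonic slope
  pooled <- do.call(rbind, lapply(co$recordings, function(r) {
    per_min <- r$sample_rate_hz * 60
    n_min <- length(r$ppg) %/% per_min
    idx <- rep(seq_len(n_min), each = per_min)
    keep <- seq_len(n_min * per_min)
    data.frame(
      gsr = as.numeric(tapply(r$gsr_conductance[keep], idx, mean)),
      h = as.numeric(tapply(r$true_hours[keep], idx, mean)))
  }))
  expect_lt(cor(pooled$gsr, pooled$h), 0)
})

test_that("shimmer CSV export round-trips and uses the documented header", {
  r <- small_cohort()$recordings[[2]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_shimmer_csv(r, path)
  header <- readLines(path, n = 1)
  expect_match(header, "GSR_Skin_Conductance_CAL")
  expect_match(header, "PPG_A13_CAL")
  expect_equal(length(readLines(path)), length(r$ppg) + 1)
  r2 <- read_shimmer_csv(path, subject_id = r$subject_id)
  expect_equal(r2$ppg, r$ppg, tolerance = 1e-8)
  expect_equal(unname(as.matrix(r2$accel)), unname(r$accel),
               tolerance = 1e-8)
  expect_equal(r2$gsr_resistance, r$gsr_resistance, tolerance = 1e-8)
  expect_equal(r2$sample_rate_hz, r$sample_rate_hz, tolerance = 1e-6)
})

test_that("reading rejects a missing mandatory channel and tolerates extras", {
  r <- toy_recording()
  path <- withr::local_tempfile(fileext = ".csv")
  write_shimmer_csv(r, path)
  df <- utils::read.csv(path, check.names = FALSE)
  df$PPG_A13_CAL <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE, quote = FALSE)
  expect_error(read_shimmer_csv(path2), "PPG_A13_CAL")

  df2 <- utils::read.csv(path, check.names = FALSE)
  df2$Battery_CAL <- 3.7
  path3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, path3, row.names = FALSE, quote = FALSE)
  expect_warning(r3 <- read_shimmer_csv(path3), "Battery_CAL")
  expect_equal(r3$ppg, r$ppg, tolerance = 1e-8)
})

test_that("profile sidecar round-trips", {
  co <- small_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(co$profiles, path)
  p <- read_profiles_csv(path)
  expect_equal(p$subject_id, co$profiles$subject_id)
  expect_equal(p$last_drink_time, co$profiles$last_drink_time)
  expect_true(all(p$gender %in% c(0, 1)))
})
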