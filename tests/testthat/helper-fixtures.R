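# Shared fixtures, built once per test session and cached. Sizes are kept
# small (tens of minutes of signal at 32 Hz) so the whole suite runs in a
# few minutes on one CPU.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# Small three-subject cohort with default (linear, negative-slope) link.
small_cohort <- function() {
  fixture("small_cohort", function() {
    cfg <- sim_config(n_subjects = 3, duration_min = c(12, 10, 10),
                      sample_rate_hz = 32, seed = 7)
    generate_cohort(cfg)
  })
}

small_feat1 <- function() {
  fixture("small_feat1", function() {
    build_feature_matrix(small_cohort(), "FEAT1")
  })
}

# Cohort with a deliberately non-linear (quadratic) dehydration link and
# per-subject tonic offsets: the fixture for the model-comparison and
# transfer-learning expectations.
eval_feat1 <- function() {
  fixture("eval_feat1", function() {
    cfg <- sim_config(n_subjects = 6, duration_min = 25,
                      sample_rate_hz = 32, gsr_link = "quadratic",
                      subject_gsr_sd = 1.5, seed = 11)
    build_feature_matrix(generate_cohort(cfg), "FEAT1")
  })
}

eval_report <- function() {
  fixture("eval_report", function() {
    run_comparison(eval_feat1(), n_runs = 3, seed = 5)
  })
}

transfer_fixture <- function() {
  fixture("transfer_report", function() {
    transfer_eval(eval_feat1(), seed = 9)
  })
}

# Per-minute heart-rate recovery error across the true-rate grid, with
# motion artifacts active at the generator defaults.
hr_grid_mae <- function() {
  fixture("hr_grid", function() {
    vapply(c(50, 60, 75, 90, 120), function(bpm) {
      cfg <- sim_config(n_subjects = 1, duration_min = 5,
                        sample_rate_hz = 32, base_bpm = bpm,
                        hr_slope_per_hour = 0, subject_bpm_sd = 0,
                        seed = 100 + bpm)
      r <- generate_cohort(cfg)$recordings[[1]]
      mf <- ppg_minute_features(r)
      true_bpm <- 60 / mean(diff(r$true_beats))
      mean(abs(mf$bpm - true_bpm))
    }, numeric(1))
  })
}

# One noise-free, motion-free, drift-free recording at exactly 60 bpm.
quiet_recording <- function() {
  fixture("quiet_recording", function() {
    cfg <- sim_config(
      n_subjects = 1, duration_min = 3, sample_rate_hz = 32,
      base_bpm = 60, rr_sd_ms = 0, motion_artifact_gain = 0,
      hr_slope_per_hour = 0, subject_bpm_sd = 0, subject_gsr_sd = 0,
      out_of_range_spike_prob = 0,
      noise_sd = list(accel = 0.3, mag = 0.05, gyro = 3, gsr = 0.05,
                      ppg = 0, temperature = 0, pressure = 0),
      seed = 3)
    generate_cohort(cfg)$recordings[[1]]
  })
}

# Minimal hand-built recording for unit tests that do not need realism.
toy_recording <- function(n_minutes = 3, fs = 4, value = 2) {
  n <- n_minutes * 60 * fs
  structure(list(
    subject_id = "T1",
    timestamp = seq(0, by = 1 / fs, length.out = n) + 1.6e9,
    accel = matrix(value, n, 3),
    mag = matrix(0.5, n, 3),
    gyro = matrix(1, n, 3),
    gsr_conductance = rep(5, n),
    gsr_resistance = rep(200, n),
    ppg = rep(2900, n),
    temperature = rep(34.9, n),
    pressure = rep(99.7, n),
    sample_rate_hz = fs
  ), class = "raw_recording")
}
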