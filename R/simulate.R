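#' Simulation configuration for a synthetic wearable cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' generator emulates a Shimmer3 GSR+ wrist unit: 3-axis accelerometer
#' (m/s^2), magnetometer (Ga) and gyroscope (deg/s), skin conductance (uS)
#' and resistance (kOhm), an ear-lobe PPG channel, and near-constant ambient
#' temperature (degC) and barometric pressure (kPa). A latent
#' hours-since-last-drinking trajectory `h(t)` advances with wall time from
#' each subject's last-drink timestamp and drives the tonic skin-conductance
#' level and the heart rate through configurable slopes, so the regression
#' target is learnable by construction.
#'
#' Activity is a two-state (rest/active) Markov chain sampled once per
#' second; in the active state gyroscope/accelerometer noise variance is
#' inflated 20-fold and motion artifact leaks into the PPG channel in
#' proportion to the instantaneous gyroscope signal. RR intervals are drawn
#' around `60000/bpm(t)` with a Gaussian jitter of `0.8 * rr_sd_ms` plus a
#' respiratory sinus-arrhythmia sinusoid of amplitude `0.6 * rr_sd_ms` at
#' `breathing_rate_hz`, so `rr_sd_ms = 0` yields a strictly periodic pulse
#' train. Each beat is a fixed two-Gaussian pulse template (systolic peak +
#' dicrotic bump), amplitude-modulated at the breathing rate.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param duration_min per-subject recording durations in minutes (recycled
#'   to `n_subjects`); each must be at least 2 so that one-minute
#'   aggregation is possible.
#' @param sample_rate_hz sampling frequency of every channel, Hz. 512 Hz is
#'   the device default; 64 Hz is the package default since the analysis
#'   operates on one-minute aggregates. Must be at least 8.
#' @param activity_transition 2x2 row-stochastic matrix of per-second
#'   transition probabilities between rest (row/col 1) and active
#'   (row/col 2) states.
#' @param base_bpm cohort-mean resting heart rate, beats/min.
#' @param rr_sd_ms overall RR-interval variability scale, ms (see Details).
#' @param breathing_rate_hz respiratory frequency, Hz.
#' @param motion_artifact_gain dimensionless gain of the gyroscope-driven
#'   additive PPG artifact during active periods; 0 disables it.
#' @param gsr_tonic_slope_per_hour drift of tonic skin conductance per hour
#'   since last drink, uS/h (negative: conductance falls as dehydration
#'   proceeds; the sign is configurable).
#' @param hr_slope_per_hour drift of heart rate per hour since last drink,
#'   bpm/h.
#' @param gsr_link `"linear"` links the tonic conductance level linearly to
#'   `h(t)`; `"quadratic"` uses `h^2/6`, a deliberately non-linear link used
#'   to exercise non-linear learners.
#' @param subject_gsr_sd,subject_bpm_sd standard deviations of per-subject
#'   random offsets on the tonic conductance level (uS) and resting heart
#'   rate (bpm); these subject-specific biases are what the
#'   transfer-learning personalization protocol can absorb.
#' @param noise_sd named list of additive white-noise standard deviations
#'   per channel (`accel`, `mag`, `gyro`, `gsr`, `ppg`, `temperature`,
#'   `pressure`), in each channel's native unit.
#' @param out_of_range_spike_prob per-sample, per-axis probability that the
#'   accelerometer emits an out-of-range reading beyond +/-16 m/s^2
#'   (exercises clipping).
#' @param scr_rate_per_min Poisson rate of phasic skin-conductance responses
#'   per minute, length-2 vector `c(rest, active)`.
#' @param fasting_hours_range range (hours) from which each subject's
#'   fasting duration at recording start is drawn uniformly.
#' @param seed integer seed; identical `(config, seed)` gives identical
#'   output.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [generate_cohort()], [study_cohort_config()]
#' @export
sim_config <- function(n_subjects = 6,
                       duration_min = rep(20, n_subjects),
                       sample_rate_hz = 64,
                       activity_transition = matrix(c(0.95, 0.05,
                                                      0.10, 0.90),
                                                    2, 2, byrow = TRUE),
                       base_bpm = 78,
                       rr_sd_ms = 40,
                       breathing_rate_hz = 0.22,
                       motion_artifact_gain = 1,
                       gsr_tonic_slope_per_hour = -0.15,
                       hr_slope_per_hour = 0.8,
                       gsr_link = c("linear", "quadratic"),
                       subject_gsr_sd = 0.6,
                       subject_bpm_sd = 3,
                       noise_sd = list(accel = 0.3, mag = 0.05, gyro = 3,
                                       gsr = 0.05, ppg = 20,
                                       temperature = 0.05, pressure = 0.02),
                       out_of_range_spike_prob = 5e-4,
                       scr_rate_per_min = c(1, 4),
                       fasting_hours_range = c(1, 12),
                       seed = 1L) {
  gsr_link <- match.arg(gsr_link)
  duration_min <- rep_len(as.numeric(duration_min), n_subjects)
  if (any(!is.finite(duration_min)) || any(duration_min <= 0))
    stop("all per-subject durations must be positive", call. = FALSE)
  if (any(duration_min < 2))
    stop("durations below 2 min cannot form one-minute aggregation intervals",
         call. = FALSE)
  if (!is.matrix(activity_transition) ||
      !all(dim(activity_transition) == c(2, 2)) ||
      any(activity_transition < 0) ||
      any(abs(rowSums(activity_transition) - 1) > 1e-8))
    stop("activity_transition must be a 2x2 row-stochastic matrix",
         call. = FALSE)
  if (sample_rate_hz < 8)
    stop("sample_rate_hz must be at least 8 Hz to resolve the pulse template",
         call. = FALSE)
  needed <- c("accel", "mag", "gyro", "gsr", "ppg", "temperature", "pressure")
  if (!all(needed %in% names(noise_sd)))
    stop("noise_sd must name all channels: ",
         paste(setdiff(needed, names(noise_sd)), collapse = ", "),
         call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects),
    duration_min = duration_min,
    sample_rate_hz = sample_rate_hz,
    activity_transition = activity_transition,
    base_bpm = base_bpm,
    rr_sd_ms = rr_sd_ms,
    breathing_rate_hz = breathing_rate_hz,
    motion_artifact_gain = motion_artifact_gain,
    gsr_tonic_slope_per_hour = gsr_tonic_slope_per_hour,
    hr_slope_per_hour = hr_slope_per_hour,
    gsr_link = gsr_link,
    subject_gsr_sd = subject_gsr_sd,
    subject_bpm_sd = subject_bpm_sd,
    noise_sd = noise_sd,
    out_of_range_spike_prob = out_of_range_spike_prob,
    scr_rate_per_min = scr_rate_per_min,
    fasting_hours_range = fasting_hours_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Configuration matching the study cohort's recording durations
#'
#' Eleven subjects with per-subject recording durations of 1768, 636, 182,
#' 573, 82, 23, 24, 21, 23, 22 and 32 minutes — a heterogeneous design
#' totalling 3386 min (56.4 h).
#'
#' @param ... overrides passed on to [sim_config()].
#' @return A `"sim_config"` object with `n_subjects = 11` and the durations
#'   above.
#' @export
study_cohort_config <- function(...) {
  durations <- c(1768, 636, 182, 573, 82, 23, 24, 21, 23, 22, 32)
  sim_config(n_subjects = 11L, duration_min = durations, ...)
}

# Run code under a seed without disturbing the caller's RNG stream.
with_sim_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Two-Gaussian pulse template on beat phase in [0, 1): systolic peak near
# 0.25 plus a dicrotic bump near 0.62. Widths chosen so the fundamental
# dominates the harmonic series of the resulting pulse train.
pulse_template <- function(phase) {
  exp(-(phase - 0.25)^2 / (2 * 0.11^2)) +
    0.45 * exp(-(phase - 0.62)^2 / (2 * 0.16^2))
}

# Per-second two-state activity chain expanded to per-sample states.
# Returns integer vector, 1 = rest, 2 = active.
simulate_activity <- function(n_seconds, trans) {
  states <- integer(n_seconds)
  s <- 1L
  u <- stats::runif(n_seconds)
  for (i in seq_len(n_seconds)) {
    s <- if (u[i] < trans[s, s]) s else (3L - s)
    states[i] <- s
  }
  states
}

# Exponential-decay skin-conductance-response kernel sampled at fs.
scr_kernel <- function(fs) {
  t <- seq(0, 8, by = 1 / fs)
  k <- exp(-t / 3) - exp(-t / 0.7)
  k / max(k)
}

simulate_recording <- function(cfg, profile, start_time, duration_min) {
  fs <- cfg$sample_rate_hz
  n <- round(duration_min * 60 * fs)
  t_rel <- (seq_len(n) - 1) / fs                 # seconds from record start
  t_abs <- start_time + t_rel                    # epoch seconds
  h <- (t_abs - profile$last_drink_time) / 3600  # hours since last drink

  n_sec <- ceiling(n / fs)
  state_sec <- simulate_activity(n_sec, cfg$activity_transition)
  state <- rep(state_sec, each = fs)[seq_len(n)]
  active <- state == 2L

  ns <- cfg$noise_sd

  ## gyroscope: rest noise, 20x variance when active, slow baseline wobble
  gyro_sd <- ns$gyro * ifelse(active, sqrt(20), 1)
  gyro <- sapply(1:3, function(a) {
    1.5 * sin(2 * pi * 0.01 * t_rel + a) + stats::rnorm(n, 0, gyro_sd)
  })
  colnames(gyro) <- c("x", "y", "z")

  ## accelerometer: slowly rotating gravity vector + motion noise + spikes
  drift <- cumsum(stats::rnorm(n_sec, 0, 0.02))
  theta <- stats::approx(seq_len(n_sec), drift, xout = (t_rel + 1),
                         rule = 2)$y
  acc_sd <- ns$accel * ifelse(active, sqrt(20), 1)
  accel <- cbind(
    x = 9.81 * sin(theta) + stats::rnorm(n, 0, acc_sd),
    y = 9.81 * sin(theta / 2) * 0.3 + stats::rnorm(n, 0, acc_sd),
    z = 9.81 * cos(theta) + stats::rnorm(n, 0, acc_sd)
  )
  if (cfg$out_of_range_spike_prob > 0) {
    spikes <- stats::runif(3L * n) < cfg$out_of_range_spike_prob
    if (any(spikes)) {
      k <- sum(spikes)
      accel[spikes] <- sample(c(-1, 1), k, replace = TRUE) *
        stats::runif(k, 17, 28)
    }
  }

  ## magnetometer: slowly varying orientation-dependent field + motion bursts
  mag_sd <- ns$mag * ifelse(active, sqrt(20), 1)
  mag <- cbind(
    x = 0.45 * cos(theta) + stats::rnorm(n, 0, mag_sd),
    y = 0.30 * sin(theta) + stats::rnorm(n, 0, mag_sd),
    z = 0.35 + 0.1 * sin(2 * pi * 0.005 * t_rel) + stats::rnorm(n, 0, mag_sd)
  )

  ## GSR: tonic level linked to h(t) + per-subject offset + phasic SCRs
  link <- switch(cfg$gsr_link,
                 linear = h,
                 quadratic = h^2 / 6)
  tonic <- 5 + profile$gsr_offset + cfg$gsr_tonic_slope_per_hour * link
  scr_p <- cfg$scr_rate_per_min[state] / (60 * fs)
  impulses <- as.numeric(stats::runif(n) < scr_p) * stats::rexp(n, 1 / 0.3)
  phasic <- if (any(impulses > 0)) {
    kern <- scr_kernel(fs)
    ph <- stats::convolve(impulses, rev(kern), type = "open")[seq_len(n)]
    ph
  } else rep(0, n)
  conductance <- tonic + phasic + stats::rnorm(n, 0, ns$gsr)
  conductance <- pmax(conductance, 0.2)   # physically positive
  resistance <- 1000 / conductance        # exact reciprocity, uS vs kOhm

  ## PPG: beats at RR intervals around 60000/bpm(t), pulse template,
  ## respiratory amplitude modulation, motion artifact, white noise
  bpm_of <- function(tt) {
    hh <- (start_time + tt - profile$last_drink_time) / 3600
    cfg$base_bpm + profile$bpm_offset + cfg$hr_slope_per_hour * hh
  }
  dur_s <- n / fs
  beats <- numeric(ceiling(dur_s * 4) + 16)
  rrs <- numeric(length(beats))
  tb <- stats::runif(1, 0, 60 / bpm_of(0))
  k <- 0L
  while (tb < dur_s + 2) {
    rr_ms <- 60000 / bpm_of(tb) +
      0.6 * cfg$rr_sd_ms * sin(2 * pi * cfg$breathing_rate_hz * tb) +
      stats::rnorm(1, 0, 0.8 * cfg$rr_sd_ms)
    rr_ms <- max(rr_ms, 250)
    k <- k + 1L
    beats[k] <- tb
    rrs[k] <- rr_ms / 1000
    tb <- tb + rr_ms / 1000
  }
  beats <- beats[seq_len(k)]
  rrs <- rrs[seq_len(k)]
  idx <- findInterval(t_rel, beats)
  prev_beat <- ifelse(idx >= 1, beats[pmax(idx, 1)], beats[1] - rrs[1])
  prev_rr <- ifelse(idx >= 1, rrs[pmax(idx, 1)], rrs[1])
  phase <- (t_rel - prev_beat) / prev_rr
  resp_mod <- 1 + 0.25 * sin(2 * pi * cfg$breathing_rate_hz * t_rel)
  ppg <- 2900 + 400 * resp_mod * pulse_template(phase)
  if (cfg$motion_artifact_gain > 0) {
    artifact <- cfg$motion_artifact_gain * 5 *
      (gyro[, 1] - 1.5 * sin(2 * pi * 0.01 * t_rel + 1)) * active
    ppg <- ppg + artifact
  }
  ppg <- ppg + stats::rnorm(n, 0, ns$ppg)

  temperature <- 34.9 + 0.2 * sin(2 * pi * t_rel / 3600) +
    stats::rnorm(n, 0, ns$temperature)
  pressure <- 99.7 + stats::rnorm(n, 0, ns$pressure)

  structure(list(
    subject_id = profile$subject_id,
    timestamp = t_abs,
    accel = accel,
    mag = mag,
    gyro = gyro,
    gsr_conductance = conductance,
    gsr_resistance = resistance,
    ppg = ppg,
    temperature = temperature,
    pressure = pressure,
    sample_rate_hz = fs,
    true_beats = beats[beats >= 0 & beats <= dur_s],
    true_hours = h
  ), class = "raw_recording")
}

#' Generate a synthetic cohort of wearable recordings
#'
#' Draws per-subject demographic profiles and one multi-channel recording
#' per subject under the configuration's latent dehydration link (see
#' [sim_config()]). Height and weight are drawn with positive covariance
#' (weight regressed on height), mirroring their strong correlation in
#' wrist-wearable cohorts.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `profiles` (data frame: `subject_id`, `age`,
#'   `height` cm, `weight` kg, `gender` coded 0 female / 1 male,
#'   `last_drink_time` epoch seconds) and `recordings` (list of
#'   `raw_recording` objects; fields `true_beats` and `true_hours` carry the
#'   simulation ground truth for validation and are not part of the sensor
#'   export).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, {
    n <- config$n_subjects
    height <- stats::rnorm(n, 159, 7)
    weight <- 63 + 0.8 * (height - 159) + stats::rnorm(n, 0, 5)
    profiles <- data.frame(
      subject_id = sprintf("S%d", seq_len(n)),
      age = pmax(18, round(stats::rnorm(n, 30, 8))),
      height = round(height, 1),
      weight = round(pmax(weight, 40), 1),
      gender = stats::rbinom(n, 1, 2 / 11),
      stringsAsFactors = FALSE
    )
    base_start <- as.numeric(as.POSIXct("2022-03-01 09:00:00", tz = "UTC"))
    start_times <- base_start + (seq_len(n) - 1) * 86400
    fasting_h <- stats::runif(n, config$fasting_hours_range[1],
                              config$fasting_hours_range[2])
    profiles$last_drink_time <- start_times - fasting_h * 3600
    profiles$gsr_offset <- stats::rnorm(n, 0, config$subject_gsr_sd)
    profiles$bpm_offset <- stats::rnorm(n, 0, config$subject_bpm_sd)

    recordings <- vector("list", n)
    for (i in seq_len(n)) {
      recordings[[i]] <- simulate_recording(
        config, profiles[i, ], start_times[i], config$duration_min[i])
    }
    names(recordings) <- profiles$subject_id
    list(profiles = profiles, recordings = recordings)
  })
}

#' Total recorded duration of a cohort in minutes
#'
#' @param cohort result of [generate_cohort()].
#' @return Total duration across recordings, minutes.
#' @export
total_duration_min <- function(cohort) {
  sum(vapply(cohort$recordings,
             function(r) length(r$ppg) / r$sample_rate_hz / 60,
             numeric(1)))
}
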