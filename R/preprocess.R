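#' Clip out-of-range per-axis sensor readings
#'
#' Readings beyond `+/-limit` are replaced by the limit in the same
#' direction; in-range samples pass through unchanged. Clipping is
#' idempotent and sign-preserving. The accelerometer's calibrated range is
#' +/-16 m/s^2, so its magnitude after clipping is bounded by `16*sqrt(3)`.
#'
#' @param xyz numeric vector or n x 3 matrix of per-axis values.
#' @param limit positive clipping bound (default 16).
#' @return Object of the same shape with every value in `[-limit, limit]`.
#' @export
clip_axes <- function(xyz, limit = 16) {
  if (!is.numeric(limit) || length(limit) != 1 || limit <= 0)
    stop("limit must be a positive scalar", call. = FALSE)
  pmin(pmax(xyz, -limit), limit)
}

#' Euclidean magnitude of a 3-axis signal
#'
#' `sqrt(x^2 + y^2 + z^2)` per sample; rotation-invariant and at least as
#' large as each axis' absolute value.
#'
#' @param x either a numeric vector (with `y`, `z` supplied) or an n x 3
#'   matrix of axis columns.
#' @param y,z per-axis values when `x` is a vector.
#' @return Numeric vector of magnitudes.
#' @export
vector_magnitude <- function(x, y = NULL, z = NULL) {
  m <- if (is.matrix(x)) x else cbind(x, y, z)
  if (ncol(m) != 3) stop("three axes required", call. = FALSE)
  sqrt(rowSums(m^2))
}

#' Cumulative change (running sum of absolute first differences)
#'
#' The per-sample absolute change in a magnitude series is the motion jerk
#' for the accelerometer; its running sum quantifies accumulated activity
#' from the start of the recording session. `out[1] = 0` and
#' `out[t] = sum_{j<t} |m[j+1] - m[j]|`; the result is non-negative,
#' non-decreasing and invariant to constant offsets.
#'
#' @param magnitude numeric series of length >= 1.
#' @return Numeric series of the same length.
#' @export
cumulative_change <- function(magnitude) {
  if (length(magnitude) == 0)
    stop("cumulative_change needs at least one sample", call. = FALSE)
  if (length(magnitude) == 1) return(0)
  c(0, cumsum(abs(diff(magnitude))))
}

#' Derived kinematic series for a recording
#'
#' Applies per-axis clipping to the accelerometer (the only channel with a
#' documented +/-16 range), then computes the three vector magnitudes and
#' their cumulative changes.
#'
#' @param recording a `raw_recording`.
#' @param clip_limit accelerometer clipping bound, m/s^2.
#' @return Data frame with columns `Accel_mag`, `Mag_mag`, `Gyro_mag`,
#'   `cumAccel`, `cumMag`, `cumGyro` (one row per sample).
#' @export
compute_kinematics <- function(recording, clip_limit = 16) {
  stopifnot(inherits(recording, "raw_recording"))
  accel <- clip_axes(recording$accel, clip_limit)
  accel_mag <- vector_magnitude(accel)
  mag_mag <- vector_magnitude(recording$mag)
  gyro_mag <- vector_magnitude(recording$gyro)
  data.frame(
    Accel_mag = accel_mag,
    Mag_mag = mag_mag,
    Gyro_mag = gyro_mag,
    cumAccel = cumulative_change(accel_mag),
    cumMag = cumulative_change(mag_mag),
    cumGyro = cumulative_change(gyro_mag)
  )
}

# Complete-minute index per sample (1-based); trailing partial minute is
# marked NA. Minutes are anchored to the first sample, not calendar time.
minute_index <- function(n_samples, sample_rate_hz) {
  per_min <- round(60 * sample_rate_hz)
  n_min <- n_samples %/% per_min
  idx <- rep(NA_integer_, n_samples)
  if (n_min > 0)
    idx[seq_len(n_min * per_min)] <- rep(seq_len(n_min), each = per_min)
  idx
}

#' Aggregate a recording and derived series to one-minute intervals
#'
#' Downsamples every channel to one row per complete minute (effective
#' output rate 1/60 Hz, i.e. 0.017 Hz) using the arithmetic mean of that
#' minute's samples. The trailing partial minute is dropped. Minute
#' boundaries are anchored to the first sample timestamp.
#'
#' @param recording a `raw_recording`.
#' @param kinematics optional result of [compute_kinematics()]; computed if
#'   missing.
#' @return Data frame with one row per complete minute: `minute_index`,
#'   `minute_time` (epoch seconds of the minute start), the mean of every
#'   raw channel under its calibrated export name, and the mean of each
#'   derived kinematic series.
#' @export
aggregate_minutes <- function(recording, kinematics = NULL) {
  stopifnot(inherits(recording, "raw_recording"))
  fs <- recording$sample_rate_hz
  n <- length(recording$ppg)
  if (n < 2 * round(60 * fs))
    stop("recording shorter than 2 full minutes cannot be aggregated",
         call. = FALSE)
  if (is.null(kinematics)) kinematics <- compute_kinematics(recording)
  idx <- minute_index(n, fs)
  keep <- !is.na(idx)
  f <- idx[keep]
  channels <- data.frame(
    PPG_A13_CAL = recording$ppg,
    GSR_Skin_Conductance_CAL = recording$gsr_conductance,
    GSR_Skin_Resistance_CAL = recording$gsr_resistance,
    Temperature_BMP280_CAL = recording$temperature,
    Pressure_BMP280_CAL = recording$pressure,
    check.names = FALSE
  )
  all_cols <- cbind(channels, kinematics)[keep, , drop = FALSE]
  counts <- tabulate(f)
  means <- rowsum(as.matrix(all_cols), f) / counts
  n_min <- nrow(means)
  out <- data.frame(
    minute_index = seq_len(n_min),
    minute_time = recording$timestamp[1] + (seq_len(n_min) - 1) * 60,
    check.names = FALSE
  )
  cbind(out, as.data.frame(means, check.names = FALSE))
}
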