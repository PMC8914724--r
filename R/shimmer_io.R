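# Shimmer-export CSV dialect: comma-separated, one header row of *_CAL
# channel names, one row per sample, epoch-millisecond timestamp column.

shimmer_columns <- function() {
  c("Timestamp_Unix_CAL",
    "Accel_LN_X_CAL", "Accel_LN_Y_CAL", "Accel_LN_Z_CAL",
    "Mag_X_CAL", "Mag_Y_CAL", "Mag_Z_CAL",
    "Gyro_X_CAL", "Gyro_Y_CAL", "Gyro_Z_CAL",
    "GSR_Skin_Conductance_CAL", "GSR_Skin_Resistance_CAL",
    "PPG_A13_CAL", "Temperature_BMP280_CAL", "Pressure_BMP280_CAL")
}

#' Write a recording as a Shimmer-style calibrated CSV export
#'
#' One header row with the calibrated channel names
#' (`PPG_A13_CAL`, `GSR_Skin_Conductance_CAL`, ...), one row per sample,
#' timestamps in epoch milliseconds. Round-trips losslessly through
#' [read_shimmer_csv()] up to float formatting precision.
#'
#' @param recording a `raw_recording` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_shimmer_csv <- function(recording, path) {
  stopifnot(inherits(recording, "raw_recording"))
  df <- data.frame(
    Timestamp_Unix_CAL = recording$timestamp * 1000,
    Accel_LN_X_CAL = recording$accel[, 1],
    Accel_LN_Y_CAL = recording$accel[, 2],
    Accel_LN_Z_CAL = recording$accel[, 3],
    Mag_X_CAL = recording$mag[, 1],
    Mag_Y_CAL = recording$mag[, 2],
    Mag_Z_CAL = recording$mag[, 3],
    Gyro_X_CAL = recording$gyro[, 1],
    Gyro_Y_CAL = recording$gyro[, 2],
    Gyro_Z_CAL = recording$gyro[, 3],
    GSR_Skin_Conductance_CAL = recording$gsr_conductance,
    GSR_Skin_Resistance_CAL = recording$gsr_resistance,
    PPG_A13_CAL = recording$ppg,
    Temperature_BMP280_CAL = recording$temperature,
    Pressure_BMP280_CAL = recording$pressure,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Shimmer-style calibrated CSV export
#'
#' Parses a file written in the calibrated Shimmer export dialect into a
#' `raw_recording`. Unknown columns are tolerated (parsed, then ignored
#' with a warning); a missing mandatory channel is a schema error naming
#' the column. The sample rate is inferred from the median timestamp step.
#'
#' @param path CSV file path.
#' @param subject_id optional subject label attached to the recording.
#' @return A `raw_recording` object.
#' @export
read_shimmer_csv <- function(path, subject_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- shimmer_columns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing mandatory channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), need)
  if (length(extra))
    warning("ignoring unrecognized column(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  bad <- !stats::complete.cases(df[need])
  if (any(bad))
    stop("malformed rows (non-numeric or missing cells) at line(s): ",
         paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
         call. = FALSE)
  ts <- df$Timestamp_Unix_CAL / 1000
  if (any(diff(ts) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  fs <- 1 / stats::median(diff(ts))
  structure(list(
    subject_id = subject_id,
    timestamp = ts,
    accel = as.matrix(df[c("Accel_LN_X_CAL", "Accel_LN_Y_CAL",
                           "Accel_LN_Z_CAL")]),
    mag = as.matrix(df[c("Mag_X_CAL", "Mag_Y_CAL", "Mag_Z_CAL")]),
    gyro = as.matrix(df[c("Gyro_X_CAL", "Gyro_Y_CAL", "Gyro_Z_CAL")]),
    gsr_conductance = df$GSR_Skin_Conductance_CAL,
    gsr_resistance = df$GSR_Skin_Resistance_CAL,
    ppg = df$PPG_A13_CAL,
    temperature = df$Temperature_BMP280_CAL,
    pressure = df$Pressure_BMP280_CAL,
    sample_rate_hz = round(fs, 6)
  ), class = "raw_recording")
}

#' Write and read the subject-metadata sidecar
#'
#' Small CSV keyed by `subject_id` with `age`, `height` (cm), `weight`
#' (kg), `gender` (0 female / 1 male) and `last_drink_time`
#' (epoch seconds).
#'
#' @param profiles data frame of subject profiles.
#' @param path CSV path.
#' @return `path` (writer) or the profiles data frame (reader).
#' @export
write_profiles_csv <- function(profiles, path) {
  cols <- c("subject_id", "age", "height", "weight", "gender",
            "last_drink_time")
  utils::write.csv(profiles[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "height", "weight", "gender",
            "last_drink_time")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("profile sidecar missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
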