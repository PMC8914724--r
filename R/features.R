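# FEAT1 / FEAT2 assembly and feature diagnostics.

feat1_columns <- c(
  "PPG_A13_CAL", "bpm", "ibi", "breathingrate", "RMSSD",
  "GSR_Skin_Resistance_CAL", "GSR_Skin_Conductance_CAL",
  "Accel_mag", "Mag_mag", "Gyro_mag", "cumAccel", "cumMag", "cumGyro",
  "Temperature_BMP280_CAL", "Pressure_BMP280_CAL",
  "age", "height", "weight", "gender")

feat2_columns <- c(
  "PPG_A13_CAL", "bpm", "breathingrate", "RMSSD",
  "GSR_Skin_Resistance_CAL", "GSR_Skin_Conductance_CAL",
  "motion_ratio", "Temperature_BMP280_CAL", "Pressure_BMP280_CAL",
  "age", "BMI", "gender")

#' Names of the feature columns of a feature matrix
#'
#' The target (`sinceLastDrinking`) and bookkeeping columns
#' (`subject_id`, `minute_time`) are not features.
#'
#' @param x a feature matrix from [assemble_feat1()]/[assemble_feat2()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(x) {
  setdiff(names(x), c("sinceLastDrinking", "subject_id", "minute_time",
                      "minute_index"))
}

#' Hours since last drinking for a sample timestamp
#'
#' The regression target: elapsed fractional hours between the last water
#' intake and the sample. Negative intervals (drink time after the sample)
#' are an error.
#'
#' @param row_timestamp sample timestamp(s), epoch seconds.
#' @param last_drink_time last-drink timestamp, epoch seconds.
#' @return Non-negative hours.
#' @export
target_hours <- function(row_timestamp, last_drink_time) {
  h <- (as.numeric(row_timestamp) - as.numeric(last_drink_time)) / 3600
  if (any(h < 0))
    stop("last_drink_time is after a sample timestamp", call. = FALSE)
  h
}

#' Body mass index
#'
#' @param height_cm height in centimetres.
#' @param weight_kg weight in kilograms.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' Combined motion ratio
#'
#' Sum over the three kinematic modalities of the ratio of the cumulative
#' change to the magnitude:
#' `cumAccel/Accel_mag + cumMag/Mag_mag + cumGyro/Gyro_mag`. Replaces the
#' six highly collinear magnitude/cumulative columns in FEAT2 with one
#' activity feature, computed per minute-row from that row's aggregated
#' values.
#'
#' @param rows data frame holding the six kinematic columns.
#' @return Numeric vector, one value per row.
#' @export
motion_ratio <- function(rows) {
  need <- c("Accel_mag", "Mag_mag", "Gyro_mag",
            "cumAccel", "cumMag", "cumGyro")
  missing <- setdiff(need, names(rows))
  if (length(missing))
    stop("missing kinematic column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(rows$Accel_mag <= 0) || any(rows$Mag_mag <= 0) ||
      any(rows$Gyro_mag <= 0))
    stop("zero or negative magnitude in motion_ratio input", call. = FALSE)
  rows$cumAccel / rows$Accel_mag + rows$cumMag / rows$Mag_mag +
    rows$cumGyro / rows$Gyro_mag
}

#' Assemble the 19-feature FEAT1 matrix for one subject
#'
#' Joins the per-minute aggregated channels with the per-minute beat
#' features, broadcasts the personal characteristics (age, height, weight,
#' gender coded 0/1) to every row, and attaches the target
#' `sinceLastDrinking` in hours computed from each minute's timestamp.
#'
#' @param minutes data frame from [aggregate_minutes()].
#' @param beat_minutes data frame from [ppg_minute_features()].
#' @param profile one-row data frame with `subject_id`, `age`, `height`,
#'   `weight`, `gender`, `last_drink_time`.
#' @return Feature matrix data frame (attribute `feature_set = "FEAT1"`):
#'   19 feature columns plus `sinceLastDrinking`, `subject_id` and
#'   `minute_time`.
#' @export
assemble_feat1 <- function(minutes, beat_minutes, profile) {
  need_min <- c("PPG_A13_CAL", "GSR_Skin_Resistance_CAL",
                "GSR_Skin_Conductance_CAL", "Accel_mag", "Mag_mag",
                "Gyro_mag", "cumAccel", "cumMag", "cumGyro",
                "Temperature_BMP280_CAL", "Pressure_BMP280_CAL")
  missing <- setdiff(need_min, names(minutes))
  if (length(missing))
    stop("minute features missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  need_beat <- c("bpm", "ibi", "breathingrate", "RMSSD")
  missing <- setdiff(need_beat, names(beat_minutes))
  if (length(missing))
    stop("beat features missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- merge(minutes, beat_minutes, by = "minute_index", sort = TRUE)
  if (anyNA(df[c(need_min, need_beat)]))
    stop("feature matrix has missing cells; run impute_failures first",
         call. = FALSE)
  out <- data.frame(
    PPG_A13_CAL = df$PPG_A13_CAL,
    bpm = df$bpm,
    ibi = df$ibi,
    breathingrate = df$breathingrate,
    RMSSD = df$RMSSD,
    GSR_Skin_Resistance_CAL = df$GSR_Skin_Resistance_CAL,
    GSR_Skin_Conductance_CAL = df$GSR_Skin_Conductance_CAL,
    Accel_mag = df$Accel_mag,
    Mag_mag = df$Mag_mag,
    Gyro_mag = df$Gyro_mag,
    cumAccel = df$cumAccel,
    cumMag = df$cumMag,
    cumGyro = df$cumGyro,
    Temperature_BMP280_CAL = df$Temperature_BMP280_CAL,
    Pressure_BMP280_CAL = df$Pressure_BMP280_CAL,
    age = profile$age,
    height = profile$height,
    weight = profile$weight,
    gender = profile$gender,
    sinceLastDrinking = target_hours(df$minute_time,
                                     profile$last_drink_time),
    subject_id = profile$subject_id,
    minute_time = df$minute_time,
    check.names = FALSE
  )
  structure(out, feature_set = "FEAT1")
}

#' Reduce FEAT1 to the 12-feature FEAT2 matrix
#'
#' Drops `height`/`weight` in favour of `BMI`, replaces the six kinematic
#' magnitude/cumulative columns by the combined [motion_ratio()], and
#' removes `ibi` (linearly tied to `bpm`). All other columns pass through
#' unchanged; rows are preserved.
#'
#' @param feat1 a FEAT1 matrix from [assemble_feat1()] (possibly several
#'   subjects' matrices row-bound).
#' @return Feature matrix with attribute `feature_set = "FEAT2"` and 12
#'   feature columns.
#' @export
assemble_feat2 <- function(feat1) {
  missing <- setdiff(feat1_columns, names(feat1))
  if (length(missing))
    stop("input is not FEAT1-shaped; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(
    PPG_A13_CAL = feat1$PPG_A13_CAL,
    bpm = feat1$bpm,
    breathingrate = feat1$breathingrate,
    RMSSD = feat1$RMSSD,
    GSR_Skin_Resistance_CAL = feat1$GSR_Skin_Resistance_CAL,
    GSR_Skin_Conductance_CAL = feat1$GSR_Skin_Conductance_CAL,
    motion_ratio = motion_ratio(feat1),
    Temperature_BMP280_CAL = feat1$Temperature_BMP280_CAL,
    Pressure_BMP280_CAL = feat1$Pressure_BMP280_CAL,
    age = feat1$age,
    BMI = bmi(feat1$height, feat1$weight),
    gender = feat1$gender,
    sinceLastDrinking = feat1$sinceLastDrinking,
    subject_id = feat1$subject_id,
    minute_time = feat1$minute_time,
    check.names = FALSE
  )
  structure(out, feature_set = "FEAT2")
}

#' Variance inflation factors
#'
#' For each feature j, regresses it by ordinary least squares (with
#' intercept) on all other features and reports `VIF_j = 1/(1 - R^2_j)`.
#' A perfectly collinear feature is flagged `Inf`; a constant column has
#' an undefined R^2 and is flagged `NA` with a warning rather than being
#' silently dropped.
#'
#' @param x data frame or matrix of numeric features (at least 2 columns,
#'   more rows than columns).
#' @return Named numeric vector of VIFs (each >= 1 where defined).
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("vif needs at least 2 features", call. = FALSE)
  if (nrow(x) <= ncol(x))
    stop("vif needs more rows than features", call. = FALSE)
  out <- numeric(ncol(x))
  names(out) <- names(x)
  vars <- vapply(x, stats::var, numeric(1))
  for (j in seq_len(ncol(x))) {
    if (!is.finite(vars[j]) || vars[j] < 1e-12) {
      out[j] <- NA_real_
      next
    }
    fit <- stats::lm(x[[j]] ~ ., data = x[-j])
    # perfect fits are an expected, flagged outcome here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    out[j] <- if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }
  if (anyNA(out))
    warning("constant column(s) flagged NA: ",
            paste(names(out)[is.na(out)], collapse = ", "), call. = FALSE)
  out
}

#' Pearson correlation matrix of a feature set
#'
#' Symmetric with unit diagonal; zero-variance columns give `NA` entries
#' and a warning.
#'
#' @param x data frame or matrix of numeric features (>= 2 rows).
#' @return Correlation matrix.
#' @export
feature_correlation <- function(x) {
  x <- as.matrix(as.data.frame(x))
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  suppressWarnings(cm <- stats::cor(x))
  diag(cm) <- ifelse(apply(x, 2, function(v) stats::sd(v) > 0), 1,
                     diag(cm))
  if (anyNA(cm))
    warning("zero-variance column(s) give undefined correlations",
            call. = FALSE)
  cm
}

#' Impurity-based feature importance from a random forest
#'
#' Fits a random forest of the target on the features and returns the
#' node-impurity importances normalized to sum to one.
#'
#' @param x data frame of features.
#' @param y numeric target (hours since last drinking).
#' @param ntree number of trees.
#' @param seed seed for the forest's bootstrap.
#' @return Named non-negative vector summing to 1.
#' @export
feature_importance <- function(x, y, ntree = 100, seed = 1L) {
  x <- as.data.frame(x)
  with_sim_seed(seed, {
    rf <- randomForest::randomForest(x, y, ntree = ntree)
    imp <- rf$importance[, "IncNodePurity"]
    if (sum(imp) <= 0) stop("degenerate forest importance", call. = FALSE)
    imp / sum(imp)
  })
}
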