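test_that("target hours convert timestamps to fractional hours since last drink", {
  drink <- as.numeric(as.POSIXct("2022-03-01 08:00:00", tz = "UTC"))
  expect_equal(target_hours(drink + 90 * 60, drink), 1.5)
  expect_equal(target_hours(drink, drink), 0)
  expect_equal(target_hours(drink + 16 * 3600, drink), 16)
  expect_error(target_hours(drink - 1, drink), "after")
})

test_that("BMI formula and its linearity in weight", {
  expect_equal(bmi(160, 64), 25)
  expect_equal(round(bmi(159, 63), 2), 24.92)
  expect_equal(bmi(170, 2 * 70), 2 * bmi(170, 70))
  expect_error(bmi(0, 60), "positive")
  expect_error(bmi(160, -1), "positive")
})

test_that("motion ratio sums the per-modality cum/magnitude ratios", {
  row <- data.frame(cumAccel = 100, cumMag = 200, cumGyro = 300,
                    Accel_mag = 10, Mag_mag = 2, Gyro_mag = 30)
  expect_equal(motion_ratio(row), 120)
  row0 <- transform(row, cumAccel = 0, cumMag = 0, cumGyro = 0)
  expect_equal(motion_ratio(row0), 0)
  expect_equal(motion_ratio(transform(row, cumAccel = 300, cumMag = 600,
                                      cumGyro = 900)), 360)
  expect_error(motion_ratio(transform(row, Mag_mag = 0)), "magnitude")
  expect_error(motion_ratio(row[-1]), "missing")
})

test_that("FEAT1 has exactly 19 features with the documented schema", {
  f1 <- small_feat1()
  expect_length(feature_columns(f1), 19)
  expect_setequal(feature_columns(f1),
    c("PPG_A13_CAL", "bpm", "ibi", "breathingrate", "RMSSD",
      "GSR_Skin_Resistance_CAL", "GSR_Skin_Conductance_CAL",
      "Accel_mag", "Mag_mag", "Gyro_mag", "cumAccel", "cumMag", "cumGyro",
      "Temperature_BMP280_CAL", "Pressure_BMP280_CAL",
      "age", "height", "weight", "gender"))
  expect_identical(attr(f1, "feature_set"), "FEAT1")
  expect_false(anyNA(f1[feature_columns(f1)]))
  expect_true(all(f1$sinceLastDrinking >= 0))
  expect_true(all(f1$gender %in% c(0, 1)))
  # personal features broadcast within subject
  for (s in unique(f1$subject_id))
    expect_equal(length(unique(f1$age[f1$subject_id == s])), 1)
  # one row per aggregated minute: 12 + 10 + 10
  expect_equal(nrow(f1), 32)
})

test_that("FEAT2 reduces FEAT1 to exactly 12 features, row-preserving and deterministic", {
  f1 <- small_feat1()
  f2 <- assemble_feat2(f1)
  expect_length(feature_columns(f2), 12)
  expect_equal(nrow(f2), nrow(f1))
  expect_identical(attr(f2, "feature_set"), "FEAT2")
  # stated removals/additions
  kept <- c("PPG_A13_CAL", "bpm", "breathingrate", "RMSSD",
            "GSR_Skin_Resistance_CAL", "GSR_Skin_Conductance_CAL",
            "Temperature_BMP280_CAL", "Pressure_BMP280_CAL", "age",
            "gender")
  expect_true(all(kept %in% feature_columns(f2)))
  expect_true(all(c("BMI", "motion_ratio") %in% feature_columns(f2)))
  expect_false(any(c("ibi", "height", "weight", "Accel_mag", "cumGyro")
                   %in% feature_columns(f2)))
  expect_identical(f2, assemble_feat2(f1))
  expect_error(assemble_feat2(f2), "FEAT1")
})

test_that("the target is non-decreasing within a subject's session", {
  f1 <- small_feat1()
  for (s in unique(f1$subject_id)) {
    rows <- f1[f1$subject_id == s, ]
    rows <- rows[order(rows$minute_time), ]
    expect_true(all(diff(rows$sinceLastDrinking) >= 0))
  }
})

test_that("VIF matches a brute-force per-column OLS oracle and flags degeneracies", {
  vif_oracle <- function(x) {
    x <- as.matrix(x)
    vapply(seq_len(ncol(x)), function(j) {
      yj <- x[, j]
      Z <- cbind(1, x[, -j, drop = FALSE])
      beta <- qr.coef(qr(Z), yj)
      res <- yj - Z %*% beta
      r2 <- 1 - sum(res^2) / sum((yj - mean(yj))^2)
      1 / (1 - r2)
    }, numeric(1))
  }
  set.seed(6)
  x <- matrix(rnorm(1000), 200, 5)
  expect_equal(unname(vif(x)), vif_oracle(x), tolerance = 1e-8)

  # mutually orthogonal centered columns give VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(400), 100, 4))))[, -1]
  expect_equal(unname(vif(q)), rep(1, 4), tolerance = 1e-6)

  # duplicated column is infinite
  dup <- cbind(x, x[, 1])
  expect_true(is.infinite(vif(dup)[6]))

  # constant column flagged, not dropped
  const <- cbind(x, k = 1)
  expect_warning(v <- vif(const), "constant")
  expect_true(is.na(v["k"]))
  expect_length(v, 6)

  expect_error(vif(x[, 1, drop = FALSE]), "2 features")
  expect_error(vif(x[1:4, ]), "rows")
})

test_that("correlation matrix is symmetric with unit diagonal and recovers built-in covariances", {
  set.seed(7)
  x <- cbind(a = rnorm(100))
  x <- cbind(x, b = -x[, "a"], c = rnorm(100))
  cm <- feature_correlation(x)
  expect_equal(cm["a", "a"], 1)
  expect_equal(cm["a", "b"], -1)
  expect_equal(cm, t(cm))
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
  expect_warning(feature_correlation(cbind(x, k = rep(2, 100))),
                 "zero-variance")

  # the simulated cohort draws weight with positive covariance on height
  cfg <- sim_config(n_subjects = 40, duration_min = 2,
                    sample_rate_hz = 8, seed = 13)
  profiles <- generate_cohort(cfg)$profiles
  expect_gt(cor(profiles$height, profiles$weight), 0)
})

test_that("forest importance is normalized and ranks signal above noise", {
  f1 <- small_feat1()
  x <- f1[feature_columns(f1)]
  set.seed(8)
  x$pure_noise <- rnorm(nrow(x))
  imp <- feature_importance(x, f1$sinceLastDrinking, seed = 8)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(imp >= 0))
  expect_gt(imp["GSR_Skin_Conductance_CAL"], imp["pure_noise"])

  one <- feature_importance(f1["GSR_Skin_Conductance_CAL"],
                            f1$sinceLastDrinking, seed = 8)
  expect_equal(unname(one), 1)
})
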