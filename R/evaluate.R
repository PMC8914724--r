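# Benchmark harness: repeated 70/30 comparisons of the model zoo and the
# leave-one-subject-out transfer-learning personalization protocol.

#' Compare the regression model zoo over repeated random splits
#'
#' For each run the rows are shuffled and split into train/test
#' (`test_fraction` held out, row-wise random), every configured learner is
#' fitted on the training rows and scored on the held-out rows, and the
#' per-model MAE/RMSE (hours), training time (s) and serialized model size
#' (bytes) are averaged over runs. A learner that fails in a run is
#' recorded and skipped, and the run continues.
#'
#' @param data feature matrix (from [assemble_feat1()] /
#'   [assemble_feat2()], possibly several subjects row-bound) or any data
#'   frame with a `sinceLastDrinking` column.
#' @param models subset of [hydration_methods()].
#' @param test_fraction held-out fraction per run (default 0.3).
#' @param n_runs number of repeated splits (default 10).
#' @param seed integer; run r uses `seed + r`.
#' @param hyper named list of per-model hyperparameter override lists.
#' @return Object of class `"model_report"`: data frame with one row per
#'   model (`mae`, `rmse`, `training_time_s`, `model_size_bytes`,
#'   `n_failed`), with the per-run results in attribute `"runs"`.
#' @export
run_comparison <- function(data, models = hydration_methods(),
                           test_fraction = 0.3, n_runs = 10, seed = 1L,
                           hyper = list()) {
  models <- match.arg(models, hydration_methods(), several.ok = TRUE)
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  d <- drop_meta(data)
  n <- nrow(d)
  runs <- vector("list", n_runs)
  splits <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    test_idx <- sample(n, round(test_fraction * n))
    splits[[r]] <- list(train = setdiff(seq_len(n), test_idx),
                        test = test_idx)
    train <- d[-test_idx, , drop = FALSE]
    test <- d[test_idx, , drop = FALSE]
    rows <- lapply(models, function(m) {
      res <- tryCatch({
        fit <- hydration_fit(sinceLastDrinking ~ ., train, method = m,
                             hyper = if (is.null(hyper[[m]])) list()
                                     else hyper[[m]])
        pred <- predict(fit, test)
        met <- regression_metrics(test$sinceLastDrinking, pred)
        data.frame(run = r, model = m, mae = met[["mae"]],
                   rmse = met[["rmse"]],
                   training_time_s = fit$training_time_s,
                   model_size_bytes = model_size(fit), failed = FALSE)
      }, error = function(e) {
        warning("model ", m, " failed in run ", r, ": ",
                conditionMessage(e), call. = FALSE)
        data.frame(run = r, model = m, mae = NA_real_, rmse = NA_real_,
                   training_time_s = NA_real_,
                   model_size_bytes = NA_integer_, failed = TRUE)
      })
      res
    })
    runs[[r]] <- do.call(rbind, rows)
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(models, function(m) {
    sub <- runs[runs$model == m & !runs$failed, , drop = FALSE]
    data.frame(
      model = m,
      mae = mean(sub$mae),
      rmse = mean(sub$rmse),
      training_time_s = mean(sub$training_time_s),
      model_size_bytes = mean(sub$model_size_bytes),
      n_failed = sum(runs$model == m & runs$failed)
    )
  }))
  structure(agg, runs = runs, splits = splits,
            class = c("model_report", "data.frame"),
            config = list(models = models, test_fraction = test_fraction,
                          n_runs = n_runs, seed = seed))
}

#' @export
print.model_report <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "Model comparison: %d run(s), %.0f/%.0f train/test split\n",
    cfg$n_runs, 100 * (1 - cfg$test_fraction), 100 * cfg$test_fraction))
  df <- as.data.frame(x)
  df$mae <- round(df$mae, 3)
  df$rmse <- round(df$rmse, 3)
  df$training_time_s <- round(df$training_time_s, 3)
  df$model_size_bytes <- round(df$model_size_bytes)
  print(df, row.names = FALSE)
  invisible(x)
}

# Personalize a base fit with a subject's rows: networks continue training
# from the base weights; other learners are re-fitted, by default on the
# pooled base + personalization rows.
personalize_fit <- function(base, train_base, train_pers, method, pooled) {
  if (method %in% c("ann", "dnn")) {
    hydration_fit(sinceLastDrinking ~ ., train_pers, method = method,
                  init = base)
  } else {
    refit_data <- if (pooled) rbind(train_base, train_pers) else train_pers
    hydration_fit(sinceLastDrinking ~ ., refit_data, method = method)
  }
}

#' Leave-one-subject-out transfer-learning personalization
#'
#' For every held-out subject and every test fraction f: a base model is
#' fitted on all other subjects' rows; a random `(1 - f)` share of the
#' held-out subject's rows personalizes it (tree/forest learners are
#' re-fitted on the pooled base + personalization rows, or on the
#' personalization rows alone with `pooled = FALSE`; the network learners
#' continue training from the base weights); both the base and the
#' personalized model are scored on the remaining fraction f of the
#' subject's rows.
#'
#' @param data feature matrix with `subject_id` and `sinceLastDrinking`.
#' @param models learners to evaluate (default the three strongest:
#'   `dnn`, `random_forest`, `extra_trees`).
#' @param test_fractions held-out test shares of the subject's rows.
#' @param seed integer seed.
#' @param pooled re-fit strategy for non-network learners (see above).
#' @param min_rows subjects with fewer rows are skipped with a warning.
#' @return Object of class `"transfer_report"`: one row per subject x
#'   fraction x model with personalized and base MAE/RMSE, personalization
#'   training time and model size; cohort means via `summary()`.
#' @export
transfer_eval <- function(data,
                          models = c("dnn", "random_forest",
                                     "extra_trees"),
                          test_fractions = c(0.3, 0.7), seed = 1L,
                          pooled = TRUE, min_rows = 10) {
  models <- match.arg(models, hydration_methods(), several.ok = TRUE)
  if (is.null(data$subject_id))
    stop("data must carry a subject_id column", call. = FALSE)
  subjects <- unique(data$subject_id)
  if (length(subjects) < 3)
    stop("transfer evaluation needs at least 3 subjects", call. = FALSE)
  d <- drop_meta(data)
  out <- list()
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    mask <- data$subject_id == s
    if (sum(mask) < min_rows) {
      warning("subject ", s, " has fewer than ", min_rows,
              " rows; skipped", call. = FALSE)
      next
    }
    train_base <- d[!mask, , drop = FALSE]
    rows_s <- d[mask, , drop = FALSE]
    for (m in models) {
      set.seed(seed + 1000L * si)
      base <- hydration_fit(sinceLastDrinking ~ ., train_base, method = m)
      for (f in test_fractions) {
        set.seed(seed + 1000L * si + round(100 * f))
        n_s <- nrow(rows_s)
        pers_idx <- sample(n_s, round((1 - f) * n_s))
        train_pers <- rows_s[pers_idx, , drop = FALSE]
        test <- rows_s[-pers_idx, , drop = FALSE]
        pers <- personalize_fit(base, train_base, train_pers, m, pooled)
        pm <- regression_metrics(test$sinceLastDrinking,
                                 predict(pers, test))
        bm <- regression_metrics(test$sinceLastDrinking,
                                 predict(base, test))
        out[[length(out) + 1L]] <- data.frame(
          subject = s, fraction = f, model = m,
          mae = pm[["mae"]], rmse = pm[["rmse"]],
          base_mae = bm[["mae"]], base_rmse = bm[["rmse"]],
          training_time_s = pers$training_time_s,
          model_size_bytes = model_size(pers))
      }
    }
  }
  if (!length(out))
    stop("no subject has at least ", min_rows, " rows", call. = FALSE)
  structure(do.call(rbind, out),
            class = c("transfer_report", "data.frame"),
            config = list(models = models,
                          test_fractions = test_fractions,
                          seed = seed, pooled = pooled))
}

#' @export
summary.transfer_report <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- stats::aggregate(
    df[c("mae", "rmse", "base_mae", "base_rmse", "training_time_s",
         "model_size_bytes")],
    by = df[c("model", "fraction")], FUN = mean)
  agg[order(agg$model, agg$fraction), ]
}

#' @export
print.transfer_report <- function(x, ...) {
  cat("Leave-one-subject-out transfer-learning personalization\n")
  cat("Cohort means per model x test fraction:\n")
  agg <- summary(x)
  num <- vapply(agg, is.numeric, logical(1))
  agg[num] <- lapply(agg[num], function(v) round(v, 3))
  print(agg, row.names = FALSE)
  invisible(x)
}
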