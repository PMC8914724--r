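# hydration_fit(): one front door to the regression model zoo used to
# predict hours since last drinking, returning a classed object with the
# usual methods. Scale-sensitive learners (regularized linear models, SVR,
# the neural networks) standardize internally; tree ensembles are fit on
# the raw feature scale.

#' Names of the supported regression learners
#'
#' `"baseline"` predicts the training-target median; `"ann"` is a
#' zero-hidden-layer (linear-activation) network; `"dnn"` a
#' single-hidden-layer perceptron; `"gbr"` gradient-boosted trees.
#'
#' @return Character vector of method names.
#' @export
hydration_methods <- function() {
  c("baseline", "linear", "lasso", "ridge", "elasticnet", "svr", "ann",
    "gbr", "dnn", "random_forest", "extra_trees")
}

default_hyper <- function(method) {
  switch(method,
    random_forest = list(ntree = 100),
    extra_trees = list(num.trees = 100),
    gbr = list(nrounds = 100, max_depth = 3, eta = 0.1),
    svr = list(cost = 1, kernel = "radial"),
    dnn = list(size = 16, decay = 1e-3, maxit = 200),
    ann = list(maxit = 200),
    lasso = list(alpha = 1),
    ridge = list(alpha = 0),
    elasticnet = list(alpha = 0.5),
    list())
}

#' Fit a time-since-drinking regression model
#'
#' Fits one of the supported learners (see [hydration_methods()]) to a
#' feature matrix with the target on the left-hand side of `formula`.
#' Training time is measured around the fit only and the serialized model
#' size is available through [model_size()]; both are informational,
#' platform-dependent quantities.
#'
#' Learners drawing random numbers (forest bootstraps, network weight
#' initialization, cross-validated penalty folds) consume the session RNG
#' stream, so results are reproducible under `set.seed()` by the caller.
#'
#' @param formula model formula, e.g. `sinceLastDrinking ~ .`; the dot
#'   expands over the columns of `data`.
#' @param data data frame of features plus the target column (use
#'   `drop_meta()` on a feature matrix to exclude bookkeeping columns).
#' @param method one of [hydration_methods()].
#' @param hyper named list of hyperparameter overrides; unset entries take
#'   pinned defaults (forests/extra trees 100 trees; boosting 100 stages of
#'   depth 3; SVR radial kernel, cost 1; penalized linear models
#'   cross-validated lambda with deterministic folds; DNN 16 hidden units,
#'   weight decay 1e-3, 200 epochs).
#' @param init optional previously fitted `hydration_fit` of the same
#'   method; for the network learners its weights warm-start training
#'   (the transfer-learning personalization step).
#' @return An object of class `"hydration_fit"` with `print`, `summary`,
#'   `coef`, `predict` and `residuals` methods.
#' @export
hydration_fit <- function(formula, data, method = hydration_methods(),
                          hyper = list(), init = NULL) {
  method <- match.arg(method)
  hp <- utils::modifyList(default_hyper(method), hyper)
  mf <- stats::model.frame(formula, data)
  tt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  if (is.null(y) || !is.numeric(y))
    stop("formula must have a numeric response", call. = FALSE)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (nrow(X) < 2 && method != "baseline")
    stop("need at least 2 training rows", call. = FALSE)

  scale_x <- method %in% c("ann", "dnn")
  if (scale_x && !is.null(init)) {
    xc <- init$x_center; xs <- init$x_scale
    yc <- init$y_center; ys <- init$y_scale
  } else if (scale_x) {
    xc <- colMeans(X)
    xs <- apply(X, 2, stats::sd)
    xs[!is.finite(xs) | xs < 1e-12] <- 1
    yc <- mean(y)
    ys <- max(stats::sd(y), 1e-12)
  } else {
    xc <- xs <- yc <- ys <- NULL
  }
  Xs <- if (scale_x) scale(X, xc, xs) else X
  ys_v <- if (scale_x) (y - yc) / ys else y

  t0 <- proc.time()[["elapsed"]]
  model <- switch(method,
    baseline = list(median = stats::median(y)),
    linear = {
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0   # aliased (constant/collinear) columns drop out
      list(coef = cf)
    },
    lasso = , ridge = , elasticnet = {
      foldid <- rep_len(1:5, nrow(X))   # deterministic folds
      cv <- glmnet::cv.glmnet(X, y, alpha = hp$alpha, foldid = foldid)
      list(cv = cv, lambda = cv$lambda.min)
    },
    svr = e1071::svm(X, y, kernel = hp$kernel, cost = hp$cost,
                     type = "eps-regression"),
    ann = {
      wts_arg <- if (!is.null(init)) list(Wts = init$model$wts) else list()
      do.call(nnet::nnet,
              c(list(x = Xs, y = ys_v, size = 0, skip = TRUE,
                     linout = TRUE, maxit = hp$maxit, trace = FALSE),
                wts_arg))
    },
    dnn = {
      wts_arg <- if (!is.null(init)) list(Wts = init$model$wts) else list()
      do.call(nnet::nnet,
              c(list(x = Xs, y = ys_v, size = hp$size, linout = TRUE,
                     decay = hp$decay, maxit = hp$maxit, trace = FALSE,
                     MaxNWts = 10000),
                wts_arg))
    },
    gbr = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(
        params = list(max_depth = hp$max_depth, eta = hp$eta,
                      objective = "reg:squarederror", nthread = 1),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    },
    random_forest = randomForest::randomForest(X, y, ntree = hp$ntree),
    extra_trees = ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = hp$num.trees,
      splitrule = "extratrees", num.random.splits = 1,
      replace = FALSE, sample.fraction = 1, num.threads = 1,
      seed = sample.int(.Machine$integer.max, 1))
  )
  elapsed <- proc.time()[["elapsed"]] - t0

  obj <- structure(list(
    method = method,
    terms = tt,
    feature_names = colnames(X),
    model = model,
    hyper = hp,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    y = y,
    training_time_s = elapsed,
    call = match.call()
  ), class = "hydration_fit")
  obj$fitted <- predict_matrix(obj, X)
  obj
}

# Predict from the numeric design matrix (no formula handling).
predict_matrix <- function(object, X) {
  m <- object$model
  switch(object$method,
    baseline = rep(m$median, nrow(X)),
    linear = as.numeric(cbind(1, X) %*% m$coef),
    lasso = , ridge = , elasticnet =
      as.numeric(stats::predict(m$cv, newx = X, s = m$lambda)),
    svr = as.numeric(stats::predict(m, X)),
    ann = , dnn = {
      Xs <- scale(X, object$x_center, object$x_scale)
      as.numeric(stats::predict(m, Xs)) * object$y_scale + object$y_center
    },
    gbr = as.numeric(stats::predict(m, xgboost::xgb.DMatrix(X))),
    random_forest = as.numeric(stats::predict(m, X)),
    extra_trees =
      stats::predict(m, data = as.data.frame(X))$predictions
  )
}

#' @export
predict.hydration_fit <- function(object, newdata, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  X <- X[, object$feature_names, drop = FALSE]
  predict_matrix(object, X)
}

#' @export
coef.hydration_fit <- function(object, ...) {
  m <- object$model
  switch(object$method,
    linear = m$coef,
    lasso = , ridge = , elasticnet = {
      b <- as.matrix(stats::coef(m$cv, s = m$lambda))
      stats::setNames(as.numeric(b), rownames(b))
    },
    NULL)
}

#' @export
residuals.hydration_fit <- function(object, ...) {
  object$y - object$fitted
}

#' @export
print.hydration_fit <- function(x, ...) {
  cat("Time-since-drinking regression (", x$method, ")\n", sep = "")
  cat("  features: ", length(x$feature_names),
      " | training rows: ", length(x$y), "\n", sep = "")
  m <- regression_metrics(x$y, x$fitted)
  cat(sprintf("  training MAE %.3f h, RMSE %.3f h\n", m["mae"], m["rmse"]))
  cat(sprintf("  training time %.2f s, serialized size %d bytes\n",
              x$training_time_s, model_size(x)))
  invisible(x)
}

#' @export
summary.hydration_fit <- function(object, ...) {
  m <- regression_metrics(object$y, object$fitted)
  out <- list(method = object$method,
              n = length(object$y),
              p = length(object$feature_names),
              train_mae = unname(m["mae"]),
              train_rmse = unname(m["rmse"]),
              training_time_s = object$training_time_s,
              model_size_bytes = model_size(object),
              coef = coef(object))
  class(out) <- "summary.hydration_fit"
  out
}

#' @export
print.summary.hydration_fit <- function(x, ...) {
  cat("Method:", x$method, "\n")
  cat(sprintf("Training rows %d, features %d\n", x$n, x$p))
  cat(sprintf("Training MAE %.3f h, RMSE %.3f h\n", x$train_mae,
              x$train_rmse))
  cat(sprintf("Training time %.2f s; serialized size %d bytes\n",
              x$training_time_s, x$model_size_bytes))
  if (!is.null(x$coef)) {
    cat("Coefficients:\n")
    print(round(x$coef, 4))
  }
  invisible(x)
}

#' Bytes of a model's canonical serialization
#'
#' The learner's serialized representation (R serialization; the native
#' raw dump for boosted trees). Platform-dependent and informational.
#'
#' @param fit a `hydration_fit`.
#' @return Integer byte count.
#' @export
model_size <- function(fit) {
  stopifnot(inherits(fit, "hydration_fit"))
  if (fit$method == "gbr")
    return(length(xgboost::xgb.save.raw(fit$model)))
  length(serialize(fit$model, NULL))
}

#' Constant predictor at the training-target median
#'
#' The comparison baseline: predicts the median of the training targets
#' for every input, which minimizes the training mean absolute error among
#' all constant predictors.
#'
#' @param train_targets non-empty numeric vector of training targets.
#' @return A function `f(n)` returning `n` copies of the median (also
#'   carries the value as attribute `"value"`).
#' @export
median_baseline <- function(train_targets) {
  if (length(train_targets) == 0)
    stop("empty training targets", call. = FALSE)
  med <- stats::median(train_targets)
  structure(function(n) rep(med, n), value = med)
}

#' Mean absolute error and root-mean-squared error
#'
#' @param y_true,y_pred equal-length numeric vectors.
#' @return Named vector `c(mae = , rmse = )`; MAE <= RMSE always.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("length mismatch between truth and prediction", call. = FALSE)
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  e <- y_true - y_pred
  c(mae = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Drop bookkeeping columns from a feature matrix
#'
#' Keeps the feature columns and the target, removing `subject_id`,
#' `minute_time` and `minute_index`, so the result can be handed to
#' `hydration_fit(sinceLastDrinking ~ ., ...)`.
#'
#' @param x feature matrix data frame.
#' @return Data frame of features + `sinceLastDrinking`.
#' @export
drop_meta <- function(x) {
  x[, c(feature_columns(x), "sinceLastDrinking"), drop = FALSE]
}
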