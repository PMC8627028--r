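#' Seeded train/test split
#'
#' @param t metrics table.
#' @param train_fraction fraction of rows for training.
#' @param seed integer seed; identical seeds give identical index sets.
#' @return list with `train`, `test` (data.frames) and `train_idx`.
#' @export
split_data <- function(t, train_fraction = 0.8, seed = 1L) {
  n <- nrow(t)
  if (n < 5L) stop("need at least 5 rows")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  withr_seed(seed, {
    n_train <- round(train_fraction * n)
    idx <- sample.int(n, n_train)
    list(train = t[idx, , drop = FALSE], test = t[-idx, , drop = FALSE],
         train_idx = sort(idx))
  })
}

MODEL_FAMILIES <- c("glm", "elastic_net", "knn", "rf", "svm_linear", "svm_poly")

# caret method + cross-validation protocol + tuning grid per family
family_spec <- function(family) {
  switch(family,
    glm = list(method = "glm",
               ctrl = caret::trainControl(method = "repeatedcv", number = 10,
                                          repeats = 10),
               grid = NULL, preproc = NULL),
    elastic_net = list(method = "glmnet",
                       ctrl = caret::trainControl(method = "cv", number = 10),
                       grid = expand.grid(alpha = seq(0, 1, by = 0.1),
                                          lambda = 10^seq(-4, 1, length.out = 10)),
                       preproc = NULL),
    knn = list(method = "knn",
               ctrl = caret::trainControl(method = "repeatedcv", number = 10,
                                          repeats = 5),
               grid = data.frame(k = seq(3, 21, by = 2)),
               preproc = c("center", "scale")),
    rf = list(method = "rf",
              ctrl = caret::trainControl(method = "cv", number = 10),
              grid = data.frame(mtry = c(2, 4, 6)),
              preproc = NULL),
    svm_linear = list(method = "svmLinear",
                      ctrl = caret::trainControl(method = "cv", number = 5),
                      grid = data.frame(C = c(0.25, 0.5, 1, 2, 4)),
                      preproc = c("center", "scale")),
    svm_poly = list(method = "svmPoly",
                    ctrl = caret::trainControl(method = "cv", number = 5),
                    grid = expand.grid(degree = 2:3, scale = 0.01,
                                       C = c(0.25, 0.5, 1, 2, 4)),
                    preproc = c("center", "scale")),
    stop("unknown model family: ", family))
}

#' Train a quality-score regression model
#'
#' Fits one of the supported regression families with cross-validated
#' hyperparameter tuning (tuning minimises CV RMSE):
#' `glm` (10-fold CV, 10 repeats), `elastic_net` (10-fold CV over an
#' alpha/lambda grid), `knn` (10-fold CV, 5 repeats, odd k 3-21,
#' standardised inputs), `rf` (10-fold CV, 500 trees, mtry in {2, 4, 6}),
#' `svm_linear` and `svm_poly` (5-fold CV, cost grid, standardised inputs;
#' polynomial degree 2-3). All randomness (folds, bootstraps) derives from
#' `seed`.
#'
#' @param train training metrics table.
#' @param family one of `glm`, `elastic_net`, `knn`, `rf`, `svm_linear`,
#'   `svm_poly`.
#' @param features feature columns the model consumes (ordered).
#' @param target target column.
#' @param seed integer seed.
#' @param n_trees forest size for `rf`.
#' @return a `QualityModel`: list with the fitted caret model, `family`,
#'   `features`, `target`, `seed`, `tuned` (chosen hyperparameters),
#'   `cv_rmse`, and a digest of the training data.
#' @export
train_model <- function(train, family = "rf",
                        features = intersect(METRIC_NAMES, colnames(train)),
                        target = "score", seed = 1L, n_trees = 500L) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (!all(features %in% colnames(train))) {
    stop("missing feature(s): ",
         paste(setdiff(features, colnames(train)), collapse = ", "))
  }
  y <- train[[target]]
  if (stats::sd(y) == 0) stop("target has zero variance")
  spec <- family_spec(family)
  if (nrow(train) < 2L * spec$ctrl$number) {
    stop("too few rows (", nrow(train), ") for ", spec$ctrl$number, "-fold CV")
  }
  x <- train[, features, drop = FALSE]
  fit <- withr_seed(seed, {
    args <- list(x = x, y = y, method = spec$method, trControl = spec$ctrl,
                 metric = "RMSE")
    if (!is.null(spec$grid)) args$tuneGrid <- spec$grid
    if (!is.null(spec$preproc)) args$preProcess <- spec$preproc
    if (family == "rf") args$ntree <- n_trees
    suppressWarnings(do.call(caret::train, args))
  })
  best <- fit$bestTune
  cv_rmse <- min(fit$results$RMSE, na.rm = TRUE)
  structure(list(fit = fit, family = family, features = features,
                 target = target, seed = seed,
                 tuned = as.list(best), cv_rmse = cv_rmse,
                 cv_protocol = spec$ctrl$method,
                 data_digest = digest_table(train[, c(features, target)])),
            class = "QualityModel")
}

# order-sensitive numeric digest of a table (training provenance)
digest_table <- function(t) {
  v <- unlist(lapply(t, as.numeric), use.names = FALSE)
  sprintf("n%d-s%.6g-ss%.6g", nrow(t), sum(v), sum(v * seq_along(v) %% 97))
}

#' @exportS3Method base::print
print.QualityModel <- function(x, ...) {
  cat(sprintf("QualityModel: %s on %d feature(s) [%s]\n", x$family,
              length(x$features), paste(x$features, collapse = ", ")))
  cat(sprintf("  tuned: %s; CV RMSE %.3f\n",
              paste(names(x$tuned), unlist(x$tuned), sep = "=", collapse = ", "),
              x$cv_rmse))
  invisible(x)
}

#' Predict quality scores
#'
#' @param object a `QualityModel`.
#' @param newdata data.frame containing the model's feature columns (extra
#'   columns are ignored; order does not matter).
#' @param ... unused.
#' @return numeric vector of predicted scores (scores above 100 are legal:
#'   they mark sequences better than the best training instance).
#' @exportS3Method stats::predict
predict.QualityModel <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) stop("missing feature(s): ", paste(missing, collapse = ", "))
  as.numeric(stats::predict(object$fit,
                            newdata = newdata[, object$features, drop = FALSE]))
}

#' Evaluate a model on held-out data
#'
#' RMSE is the root mean squared residual. R^2 is reported both as the
#' squared Pearson correlation between predictions and observed scores
#' (`r_squared`, the headline number) and as `1 - SS_res/SS_tot`
#' (`r_squared_ss`). Constant predictions leave the correlation undefined;
#' it is reported as 0 with a warning.
#'
#' @param model a `QualityModel`.
#' @param test held-out metrics table.
#' @return list with `rmse`, `r_squared`, `r_squared_ss`, `n`.
#' @export
evaluate <- function(model, test) {
  if (nrow(test) == 0L) stop("empty test set")
  obs <- test[[model$target]]
  pred <- predict(model, test)
  rmse <- sqrt(mean((pred - obs)^2))
  if (length(pred) < 2L || stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    warning("constant predictions or observations: r_squared reported as 0")
    r2 <- 0
  } else {
    r2 <- stats::cor(pred, obs)^2
  }
  r2ss <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  list(rmse = rmse, r_squared = r2, r_squared_ss = r2ss, n = nrow(test))
}

#' Select the best model family by test RMSE
#'
#' @param results named list of [evaluate()] results (one per family).
#' @return the winning family name; ties break by higher r_squared, then by
#'   the fixed family order of `MODEL_FAMILIES`.
#' @export
select_best <- function(results) {
  if (length(results) == 0L) stop("no results")
  fams <- names(results)
  ord <- order(vapply(results, `[[`, 0, "rmse"),
               -vapply(results, `[[`, 0, "r_squared"),
               match(fams, MODEL_FAMILIES))
  fams[ord[1]]
}

#' Retrain on the full table and predict
#'
#' Retrains the chosen family on every row of `t` (the standard final-model
#' refit after selection) and predicts the score of one or more metric
#' vectors.
#'
#' @param family model family.
#' @param t full metrics table.
#' @param newdata metric rows to score.
#' @param features feature columns.
#' @param target target column.
#' @param seed integer seed.
#' @return list with `model` (the refitted `QualityModel`) and `scores`.
#' @export
finalize_and_predict <- function(family, t, newdata,
                                 features = intersect(METRIC_NAMES, colnames(t)),
                                 target = "score", seed = 1L) {
  model <- train_model(t, family = family, features = features,
                       target = target, seed = seed)
  list(model = model, scores = predict(model, newdata))
}

#' Persist a model as a directory
#'
#' Writes `metadata.json` (family, features, hyperparameters, seed, CV
#' protocol, training-data digest) and `estimator.rds` (the fitted model).
#'
#' @param model a `QualityModel`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "QualityModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(family = model$family, features = model$features,
               target = model$target, seed = model$seed, tuned = model$tuned,
               cv_rmse = model$cv_rmse, cv_protocol = model$cv_protocol,
               data_digest = model$data_digest)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model, file.path(dir, "estimator.rds"))
  invisible(dir)
}

#' Load a persisted model
#'
#' @param dir directory written by [save_model()].
#' @return the `QualityModel`.
#' @export
load_model <- function(dir) {
  f <- file.path(dir, "estimator.rds")
  if (!file.exists(f)) stop("no model found under ", dir)
  model <- readRDS(f)
  if (!inherits(model, "QualityModel")) stop("not a QualityModel: ", f)
  model
}
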