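#' The eight qualification features
#'
#' Fixed feature order of the cell-qualification model: area, perimeter,
#' circularity, aspect ratio, roundness, solidity, AR x solidity and the
#' scaled perimeter-to-area ratio.
#'
#' @return character vector of column names.
#' @export
qc_feature_names <- function() {
  c("area_um2", "perimeter_um", "circularity", "aspect_ratio",
    "roundness", "solidity", "ar_x_solidity", "scaled_perimeter_area")
}

check_features <- function(data) {
  missing <- setdiff(qc_feature_names(), names(data))
  if (length(missing) > 0)
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(data[, qc_feature_names()])
  if (anyNA(X)) stop("feature table contains missing values")
  X
}

#' Train the cell-qualification model
#'
#' Fits an L2-regularized logistic regression (unit regularization
#' strength, deterministic convex solver) on standard-scaled features to
#' separate single intact rod-shaped cells (label 1) from touching,
#' rounded or fragmented objects (label 0). The data are split into a
#' stratified, seeded train/test partition; z-scoring statistics come from
#' the training split only, and held-out accuracy, precision, recall and
#' F1 are stored with the model.
#'
#' @param data data frame with the eight feature columns (see
#'   [qc_feature_names()]) and a 0/1 `label` column.
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed RNG seed for the stratified split.
#' @param threshold posterior-probability decision threshold.
#' @return An object of class `qc_model`: feature order, scaler mean/sd,
#'   weights and intercept, threshold, and `training_meta` with split
#'   sizes, seed and held-out metrics.
#' @examples
#' bench <- synth_benchmark(n_cells = 120, seed = 7)
#' m <- train_qc(bench, seed = 7)
#' m$training_meta$metrics$accuracy
#' @export
train_qc <- function(data, test_fraction = 0.2, seed = 1L,
                     threshold = 0.5) {
  if (nrow(data) < 50) stop("need at least 50 labeled rows")
  if (!"label" %in% names(data)) stop("data must carry a 0/1 label column")
  y <- as.integer(data$label)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- check_features(data)

  idx_test <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      rows <- which(y == cl)
      sample(rows, max(1L, round(length(rows) * test_fraction)))
    }), use.names = FALSE)
  })
  idx_train <- setdiff(seq_len(nrow(X)), idx_test)

  mu <- colMeans(X[idx_train, , drop = FALSE])
  sdev <- apply(X[idx_train, , drop = FALSE], 2, stats::sd)
  zero_var <- sdev <= .Machine$double.eps
  if (any(zero_var))
    stop("zero-variance feature(s) in training split: ",
         paste(names(sdev)[zero_var], collapse = ", "))
  Ztr <- scale(X[idx_train, , drop = FALSE], center = mu, scale = sdev)

  # unit regularization strength C = 1 corresponds to lambda = 1/n in the
  # per-observation-averaged ridge objective
  fit <- glmnet::glmnet(Ztr, y[idx_train], family = "binomial",
                        alpha = 0, lambda = 1 / length(idx_train),
                        standardize = FALSE, thresh = 1e-12,
                        maxit = 1e6)
  w <- as.numeric(coef(fit))
  model <- structure(
    list(feature_order = qc_feature_names(),
         scaler_mean = stats::setNames(as.numeric(mu), qc_feature_names()),
         scaler_sd = stats::setNames(as.numeric(sdev), qc_feature_names()),
         intercept = w[1],
         weights = stats::setNames(w[-1], qc_feature_names()),
         threshold = threshold,
         training_range = apply(X[idx_train, , drop = FALSE], 2, range),
         training_meta = list(n_train = length(idx_train),
                              n_test = length(idx_test),
                              test_fraction = test_fraction,
                              seed = as.integer(seed),
                              test_idx = sort(idx_test))),
    class = "qc_model")
  test_data <- data[idx_test, , drop = FALSE]
  model$training_meta$metrics <- evaluate_qc(model, test_data)
  model$training_meta$train_metrics <-
    evaluate_qc(model, data[idx_train, , drop = FALSE])
  model
}

#' @export
print.qc_model <- function(x, ...) {
  m <- x$training_meta$metrics
  cat(sprintf(paste0("<qc_model> 8-feature standard-scaled logistic ",
                     "regression\n  trained on %d cells (held-out %d): ",
                     "accuracy %.3f, precision %.3f, recall %.3f, F1 %.3f\n"),
              x$training_meta$n_train, x$training_meta$n_test,
              m$accuracy, m$precision, m$recall, m$f1))
  invisible(x)
}

qc_scores <- function(model, X) {
  Z <- scale(X[, model$feature_order, drop = FALSE],
             center = model$scaler_mean[model$feature_order],
             scale = model$scaler_sd[model$feature_order])
  eta <- drop(Z %*% model$weights[model$feature_order]) + model$intercept
  1 / (1 + exp(-eta))
}

#' Qualify cell measurements
#'
#' Applies a trained [train_qc()] model to a measurement table: each row
#' is scored with the stored scaler and weights and flagged qualified
#' (1) when the posterior reaches the model threshold, otherwise 0. Row
#' order is preserved; every table sees identical preprocessing. Rows with
#' any feature more than 10x outside the training range are still
#' classified but reported as extrapolation.
#'
#' @param model a `qc_model`.
#' @param data measurement table with the eight feature columns.
#' @return `data` with the `qualified` column filled (integer 0/1) and a
#'   `qc_score` posterior column.
#' @export
classify <- function(model, data) {
  if (nrow(data) == 0) {
    data$qualified <- integer(0)
    data$qc_score <- numeric(0)
    return(data)
  }
  X <- check_features(data)
  p <- qc_scores(model, X)
  rng <- model$training_range
  span <- rng[2, ] - rng[1, ]
  lo <- matrix(rng[1, ] - 9 * span, nrow(X), ncol(X), byrow = TRUE)
  hi <- matrix(rng[2, ] + 9 * span, nrow(X), ncol(X), byrow = TRUE)
  extrap <- rowSums(X < lo | X > hi) > 0
  if (any(extrap))
    message(sum(extrap), " row(s) lie far outside the training range ",
            "(classified, flagged as extrapolation)")
  data$qualified <- as.integer(p >= model$threshold)
  data$qc_score <- p
  attr(data, "extrapolated") <- extrap
  data
}

#' Evaluate a qualification model on labeled data
#'
#' @param model a `qc_model`.
#' @param data labeled table (eight features + `label`).
#' @return list with `accuracy`, `precision`, `recall`, `f1` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_qc <- function(model, data) {
  if (!"label" %in% names(data)) stop("data must carry a 0/1 label column")
  y <- as.integer(data$label)
  if (length(unique(y)) < 2)
    stop("both classes must be present for evaluation")
  pred <- classify(model, data)$qualified
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Persist a qualification model as JSON
#'
#' The model is stored as plain JSON (feature order, scaler statistics,
#' weights, threshold, training metadata) so it can be inspected and
#' reloaded anywhere; no binary serialization.
#'
#' @param model a `qc_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_qc_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_qc_model
#' @export
load_qc_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$feature_order <- unlist(m$feature_order)
  m$scaler_mean <- stats::setNames(unlist(m$scaler_mean), m$feature_order)
  m$scaler_sd <- stats::setNames(unlist(m$scaler_sd), m$feature_order)
  m$weights <- stats::setNames(unlist(m$weights), m$feature_order)
  m$training_range <- matrix(unlist(m$training_range), nrow = 2,
                             dimnames = list(NULL, m$feature_order))
  structure(m, class = "qc_model")
}
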