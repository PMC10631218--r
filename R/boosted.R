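# Gradient-boosted decision-tree classifier on extracted (or raw) feature
# matrices, via xgboost at its library-default hyperparameters.

default_tree_params <- function(n_classes) {
  p <- list(eta = 0.3, max_depth = 6, min_child_weight = 1, gamma = 0,
            subsample = 1, colsample_bytree = 1, lambda = 1, alpha = 0,
            tree_method = "hist", nthread = 1)
  if (n_classes > 2) {
    p$objective <- "multi:softprob"
    p$num_class <- n_classes
  } else {
    p$objective <- "binary:logistic"
  }
  p
}

#' Fit a gradient-boosted tree ensemble on a feature matrix
#'
#' Trains an xgboost classifier at the library's default hyperparameters
#' with no per-dataset optimization (100 boosting rounds, learning rate 0.3,
#' depth 6; logistic objective for binary tasks, softmax-style multiclass
#' otherwise). The exact hyperparameter set in force is snapshotted into the
#' fitted object so future library-version drift is detectable.
#'
#' @param fm A `feature_matrix` from [extract_features()], or any numeric
#'   matrix.
#' @param y Integer labels in `[0, k)`.
#' @param seed Integer seed recorded and applied to the fit.
#' @param nrounds Number of boosting rounds (default 100).
#' @param params Named list of xgboost parameter overrides (rarely needed).
#' @return A `tree_ensemble_model`.
#' @export
fit_trees <- function(fm, y, seed = 0, nrounds = 100, params = list()) {
  X <- as_feature_values(fm)
  y <- as.integer(y)
  if (nrow(X) < 2) abort("need at least 2 examples")
  if (nrow(X) != length(y)) abort("X and y disagree on the number of examples")
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("single-class input: need at least 2 classes present")
  n_classes <- max(y) + 1L
  p <- utils::modifyList(default_tree_params(n_classes), params)
  booster <- with_seed_(seed, {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    xgboost::xgb.train(params = c(p, list(seed = as.integer(seed))),
                       data = dtrain, nrounds = nrounds, verbose = 0)
  })
  structure(list(booster = booster,
                 n_features = ncol(X),
                 feature_names = colnames(X),
                 classes = classes,
                 n_classes = n_classes,
                 coords = if (inherits(fm, "feature_matrix")) fm$coords else NULL,
                 layer_name = if (inherits(fm, "feature_matrix")) fm$layer_name else NA_character_,
                 params = c(p, list(nrounds = nrounds, seed = as.integer(seed)))),
            class = "tree_ensemble_model")
}

#' @export
print.tree_ensemble_model <- function(x, ...) {
  cat(sprintf("<tree_ensemble_model> %d features, %d classes, %d rounds (objective %s)\n",
              x$n_features, x$n_classes, x$params$nrounds,
              x$params$objective))
  invisible(x)
}

#' Predict with a fitted tree ensemble
#'
#' @param object A `tree_ensemble_model`.
#' @param newdata A `feature_matrix` or numeric matrix with the same feature
#'   count as at fit time.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Integer labels, or an `n x k` probability matrix.
#' @export
predict.tree_ensemble_model <- function(object, newdata,
                                        type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_feature_values(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("feature count mismatch: model has %d features, data has %d",
                  object$n_features, ncol(X)))
  }
  raw <- predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1))
  P <- if (object$n_classes > 2) {
    if (is.matrix(raw)) raw else matrix(raw, ncol = object$n_classes,
                                        byrow = TRUE)
  } else {
    cbind(1 - raw, raw)
  }
  if (type == "prob") P else max.col(P, "first") - 1L
}

#' Classification accuracy of a model on a feature matrix
#'
#' @param model A `tree_ensemble_model`.
#' @param fm Features aligned row-by-row with `y`.
#' @param y True integer labels.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, fm, y) {
  pred <- predict(model, fm, type = "class")
  mean(pred == as.integer(y))
}

#' Rank features by information-gain importance
#'
#' Features are ranked by their total gain (split-quality improvement)
#' across the ensemble, in non-increasing order. When the model was fit on
#' an extracted `feature_matrix`, each feature is traced back to its layer
#' coordinates (position, channel).
#'
#' @param model A `tree_ensemble_model`.
#' @return A tibble with `rank`, `feature_index`, `feature_name`, `gain`,
#'   and (when available) `position` and `channel`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "tree_ensemble_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  nms <- model$feature_names %||% sprintf("f%d", seq_len(model$n_features))
  fidx <- match(imp$Feature, nms)
  if (anyNA(fidx)) fidx <- as.integer(sub("^f", "", imp$Feature)) + 1L
  out <- tibble::tibble(rank = seq_len(nrow(imp)),
                        feature_index = fidx,
                        feature_name = nms[fidx],
                        gain = imp$Gain)
  if (!is.null(model$coords)) {
    out <- dplyr::left_join(out, model$coords,
                            by = c(feature_index = "feature"))
  }
  out
}

#' @rdname feature_importance
#' @param x A `tree_ensemble_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tree_ensemble_model <- function(x, ...) feature_importance(x)

#' Export an importance ranking as TSV
#'
#' @param model A `tree_ensemble_model`.
#' @param path Output TSV path.
#' @export
write_importance_tsv <- function(model, path) {
  utils::write.table(feature_importance(model), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
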