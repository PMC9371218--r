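feature_columns <- function(features) {
  setdiff(names(features), c("slice_id", "label"))
}

check_features <- function(features) {
  if (!is.data.frame(features) ||
      !all(c("slice_id", "label") %in% names(features))) {
    stop("`features` must be a data.frame with `slice_id` and `label` columns",
         call. = FALSE)
  }
  if (length(feature_columns(features)) == 0L) {
    stop("`features` has no feature columns", call. = FALSE)
  }
  if (anyNA(features)) {
    stop("`features` contains missing values", call. = FALSE)
  }
  invisible(features)
}

#' Stratified train/test split
#'
#' Splits the manifest's slice ids into disjoint train and test sets,
#' stratified by `quality_label`: per class, `round(ratio * n)` slices go to
#' training. Deterministic for a fixed seed.
#'
#' @param manifest Manifest `data.frame`.
#' @param ratio Training fraction in `(0, 1)`; default 0.8 (the 80:20 split).
#' @param seed Integer seed.
#' @return List of class `"split_spec"` with `train_ids`, `test_ids`,
#'   `ratio`, `seed`, `stratified`.
#' @export
split_dataset <- function(manifest, ratio = 0.8, seed = 0) {
  check_manifest(manifest)
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio <= 0 || ratio >= 1) {
    stop("`ratio` must lie strictly between 0 and 1", call. = FALSE)
  }
  classes <- split(as.character(manifest$slice_id), manifest$quality_label)
  if (any(vapply(classes, length, integer(1)) < 2L)) {
    stop("each quality class needs at least 2 slices for a stratified split",
         call. = FALSE)
  }
  train_ids <- with_seed(seed, {
    unlist(lapply(classes, function(ids) {
      n_tr <- round(ratio * length(ids))
      n_tr <- max(1L, min(length(ids) - 1L, n_tr))
      sample(ids, n_tr)
    }), use.names = FALSE)
  })
  test_ids <- setdiff(as.character(manifest$slice_id), train_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids, ratio = ratio,
                 seed = seed, stratified = TRUE), class = "split_spec")
}

#' Train an artifact classifier
#'
#' Fits either an RBF-kernel support vector machine (`cost = 1`, bandwidth
#' `gamma = 1/p` on standardized features) or a 1000-tree random forest on
#' the training feature table. Features are z-score standardized with
#' center/scale estimated on the training rows only; the scaling is stored in
#' the model and re-applied at prediction time, so no test-set statistics
#' ever enter the model.
#'
#' @param features Training feature table (rows = slices) with `slice_id`,
#'   `label` and feature columns; both classes must be present.
#' @param kind `"svm_rbf"` or `"rf_1000"`.
#' @param seed Integer seed for the (random-forest) training randomness.
#' @return An object of class `"ct_classifier"`.
#' @seealso [predict_classifier()], [evaluate_model()]
#' @export
train_classifier <- function(features, kind = c("svm_rbf", "rf_1000"),
                             seed = 0) {
  kind <- match.arg(kind)
  check_features(features)
  y <- factor(as.integer(features$label), levels = c(0L, 1L))
  if (nlevels(droplevels(y)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  cols <- feature_columns(features)
  x <- as.matrix(features[, cols, drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  xs <- scale(x, center = center, scale = scale_)

  fit <- if (kind == "svm_rbf") {
    with_seed(seed, e1071::svm(x = xs, y = y, kernel = "radial", cost = 1,
                               scale = FALSE))
  } else {
    with_seed(seed, randomForest::randomForest(x = xs, y = y, ntree = 1000))
  }
  structure(list(kind = kind, fit = fit, center = center, scale = scale_,
                 feature_names = cols, seed = seed),
            class = "ct_classifier")
}

#' Predict labels and scores for a feature table
#'
#' Applies the stored training standardization, then returns hard 0/1 labels
#' plus a continuous score oriented towards the positive (artifact) class:
#' the SVM decision-function margin, or the random forest's positive-class
#' vote fraction.
#'
#' @param model A `"ct_classifier"` from [train_classifier()].
#' @param features Feature table with the same feature columns.
#' @return `data.frame` with `slice_id`, `pred` (integer 0/1), `score`.
#' @export
predict_classifier <- function(model, features) {
  if (!inherits(model, "ct_classifier")) {
    stop("`model` must come from train_classifier()", call. = FALSE)
  }
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss) > 0L) {
    stop(sprintf("features missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  xs <- scale(x, center = model$center, scale = model$scale)

  if (model$kind == "svm_rbf") {
    pr <- stats::predict(model$fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient the margin towards class "1" whatever libsvm's internal order
    lab <- colnames(dv)[1]
    score <- if (identical(lab, "1/0")) dv[, 1] else -dv[, 1]
    pred <- as.integer(as.character(pr))
  } else {
    prob <- stats::predict(model$fit, xs, type = "prob")
    score <- prob[, "1"]
    pred <- as.integer(as.character(stats::predict(model$fit, xs)))
  }
  data.frame(slice_id = if ("slice_id" %in% names(features)) {
    as.character(features$slice_id)
  } else {
    as.character(seq_len(nrow(features)))
  }, pred = pred, score = as.numeric(score), stringsAsFactors = FALSE)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann--Whitney U
#' statistic of the scores (midranks for ties). `NA` when either class is
#' absent.
#'
#' @param scores Numeric scores, larger = more artifact-like.
#' @param labels 0/1 labels, positive class 1.
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc_rank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FP+FN+TN)`, sensitivity `TP/(TP+FN)` (fraction of
#' artifact slices flagged — the clinically prioritized metric) and
#' specificity `TN/(FP+TN)`, with the artifact class positive.
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @param auc Optional AUC to carry along (default `NA`).
#' @return A list of class `"eval_report"`.
#' @examples
#' metrics_from_counts(tp = 26, fp = 10, fn = 4, tn = 20)
#' @export
metrics_from_counts <- function(tp, fp, fn, tn, auc = NA_real_) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  structure(list(
    tp = as.integer(tp), fp = as.integer(fp),
    fn = as.integer(fn), tn = as.integer(tn),
    accuracy = (tp + tn) / total,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (fp + tn > 0) tn / (fp + tn) else NA_real_,
    auc = auc
  ), class = "eval_report")
}

#' Evaluate a classifier on a labeled test table
#'
#' Hard predictions give the confusion counts (positive class = artifact,
#' label 1); the continuous scores give the AUC via the rank statistic.
#'
#' @param model A `"ct_classifier"`.
#' @param features Labeled test feature table.
#' @return An `"eval_report"` (see [metrics_from_counts()]).
#' @export
evaluate_model <- function(model, features) {
  check_features(features)
  pr <- predict_classifier(model, features)
  truth <- as.integer(features$label)
  tp <- sum(pr$pred == 1L & truth == 1L)
  fp <- sum(pr$pred == 1L & truth == 0L)
  fn <- sum(pr$pred == 0L & truth == 1L)
  tn <- sum(pr$pred == 0L & truth == 0L)
  metrics_from_counts(tp, fp, fn, tn, auc = auc_rank(pr$score, truth))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Artifact detection evaluation (positive = artifact)\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  accuracy:    %.2f%%\n", 100 * x$accuracy))
  cat(sprintf("  sensitivity: %.2f%%\n", 100 * x$sensitivity))
  cat(sprintf("  specificity: %.2f%%\n", 100 * x$specificity))
  cat(sprintf("  AUC:         %s\n",
              ifelse(is.na(x$auc), "undefined", sprintf("%.4f", x$auc))))
  invisible(x)
}
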