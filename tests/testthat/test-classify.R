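# Small synthetic feature tables for classifier-level tests: two Gaussian
# blobs in two informative dimensions plus one noise dimension.
toy_features <- function(n_per_class, sep = 3, seed = 1) {
  ids <- sprintf("t%03d", seq_len(2 * n_per_class))
  lab <- rep(c(0L, 1L), each = n_per_class)
  ctnet:::with_seed(seed, data.frame(
    slice_id = ids, label = lab,
    f1 = stats::rnorm(2 * n_per_class, mean = sep * lab),
    f2 = stats::rnorm(2 * n_per_class, mean = -sep * lab),
    f3 = stats::rnorm(2 * n_per_class),
    stringsAsFactors = FALSE))
}

toy_manifest <- function(n_per_class) {
  data.frame(slice_id = sprintf("t%03d", seq_len(2 * n_per_class)),
             region_label = 1L,
             quality_label = rep(c(0L, 1L), each = n_per_class),
             image_path = "none.png", stringsAsFactors = FALSE)
}

test_that("stratified splits have the specified per-class sizes", {
  man <- toy_manifest(300)
  sp <- split_dataset(man, ratio = 0.8, seed = 3)
  lab <- man$quality_label[match(sp$train_ids, man$slice_id)]
  expect_equal(sum(lab == 0), 240)
  expect_equal(sum(lab == 1), 240)
  expect_equal(length(sp$test_ids), 120)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), man$slice_id)

  # determinism
  sp2 <- split_dataset(man, ratio = 0.8, seed = 3)
  expect_identical(sp$train_ids, sp2$train_ids)
  expect_false(identical(sp$train_ids,
                         split_dataset(man, ratio = 0.8, seed = 4)$train_ids))

  # minimal balanced case: 1 + 1 training slices
  sp4 <- split_dataset(toy_manifest(2), ratio = 0.5, seed = 1)
  lab4 <- table(toy_manifest(2)$quality_label[
    match(sp4$train_ids, toy_manifest(2)$slice_id)])
  expect_equal(unname(as.integer(lab4)), c(1, 1))

  expect_error(split_dataset(toy_manifest(300), ratio = 1.2), "between")
  tiny <- toy_manifest(2)[c(1, 3, 4), ]
  expect_error(split_dataset(tiny, 0.8, 1), "at least 2")
})

test_that("confusion-count metrics reproduce closed forms", {
  # reconstructed confusion matrix of a 30+30 test set
  r <- metrics_from_counts(tp = 26, fp = 10, fn = 4, tn = 20)
  expect_equal(round(100 * r$sensitivity, 2), 86.67)
  expect_equal(round(100 * r$accuracy, 2), 76.67)
  expect_equal(round(100 * r$specificity, 2), 66.67)
  # identities: metrics recompute from the counts
  expect_equal(r$accuracy * (r$tp + r$fp + r$fn + r$tn), r$tp + r$tn)
  expect_identical(r$sensitivity, r$tp / (r$tp + r$fn))
  expect_identical(r$specificity, r$tn / (r$fp + r$tn))

  perfect <- metrics_from_counts(30, 0, 0, 30)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  allpos <- metrics_from_counts(30, 30, 0, 0)
  expect_equal(c(allpos$accuracy, allpos$sensitivity, allpos$specificity),
               c(0.5, 1, 0))
  expect_error(metrics_from_counts(-1, 0, 0, 1), "non-negative")
})

test_that("rank AUC equals the pairwise Mann-Whitney oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    scores <- round(stats::rnorm(n), 1)  # rounding forces ties
    pos <- scores[labels == 1L]
    neg <- scores[labels == 0L]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_rank(scores, labels), mean(cmp))
  }
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_true(is.na(auc_rank(1:4, rep(1, 4))))
})

test_that("both classifier kinds separate an easy two-feature problem", {
  train <- toy_features(10, sep = 4, seed = 2)
  for (kind in c("svm_rbf", "rf_1000")) {
    model <- train_classifier(train, kind, seed = 1)
    r <- evaluate_model(model, train)
    expect_equal(r$accuracy, 1, info = kind)
    # scores oriented towards the artifact class
    expect_equal(r$auc, 1, info = kind)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    model <- train_classifier(train, "svm_rbf", seed = 1)
    test <- toy_features(15, sep = 1.5, seed = 9)
    pr <- predict_classifier(model, test)
    expect_equal(auc_rank(pr$score, test$label),
                 as.numeric(pROC::auc(test$label, pr$score,
                                      direction = "<", quiet = TRUE)))
  }
  one_class <- toy_features(5)
  one_class$label <- 0L
  expect_error(train_classifier(one_class, "svm_rbf"), "both classes")
})

test_that("label-permuted training yields chance-level test accuracy", {
  test <- toy_features(20, sep = 3, seed = 100)
  accs <- vapply(1:20, function(s) {
    train <- toy_features(20, sep = 3, seed = s)
    train$label <- ctnet:::with_seed(1000 + s, sample(train$label))
    model <- train_classifier(train, "svm_rbf", seed = s)
    evaluate_model(model, test)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
})
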