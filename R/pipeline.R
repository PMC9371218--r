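topo_summary_as_list <- function(s) {
  if (is.null(s)) return(NULL)
  dd <- as.list(s$degree_distribution)
  list(n_vertices = s$n_vertices, n_edges = s$n_edges,
       average_degree = s$average_degree,
       average_clustering = s$average_clustering,
       average_path_length = s$average_path_length,
       degree_distribution = dd)
}

#' Run the full motion-artifact detection pipeline
#'
#' Executes, end to end: pixel-graph feature extraction for every slice ->
#' stratified train/test split -> slice-level graph built from the *training*
#' records with per-class topological summaries -> consistency check (the
#' artifact class is expected to exceed the clean class in both pixel-graph
#' average degree and average clustering; a violation raises a warning, not
#' an error) -> classifier training -> evaluation on the held-out test set.
#'
#' Quality labels are consumed only from training rows (slice-graph
#' construction, feature standardization, model fitting); test labels enter
#' the computation solely to score the final predictions.
#'
#' @param manifest Manifest `data.frame`.
#' @param classifier `"svm_rbf"` or `"rf_1000"`.
#' @param params A [graph_params()] object for the pixel graphs.
#' @param ratio Training fraction; default 0.8.
#' @param seed Integer seed driving the split and classifier training.
#' @param features Optional precomputed feature table from
#'   [extract_features()] (must cover every manifest slice); computed from
#'   the images when `NULL`.
#' @param include_topology Use the topological feature block. Default `TRUE`.
#' @param base_dir Optional base directory for relative image paths.
#' @param report_path Optional path; when set, the report is also written as
#'   JSON.
#' @return A list of class `"madm_report"`: `config`, `split`,
#'   `train_topology` (per-class slice-graph summaries plus class-mean
#'   pixel-graph features), `consistency_ok`, `eval`, `predictions`.
#' @export
run_madm_cn <- function(manifest, classifier = c("svm_rbf", "rf_1000"),
                        params = graph_params(), ratio = 0.8, seed = 0,
                        features = NULL, include_topology = TRUE,
                        base_dir = NULL, report_path = NULL) {
  classifier <- match.arg(classifier)
  check_manifest(manifest)
  if (is.null(features)) {
    features <- extract_features(manifest, params,
                                 include_topology = include_topology,
                                 base_dir = base_dir)
  } else {
    check_features(features)
    if (!all(manifest$slice_id %in% features$slice_id)) {
      stop("`features` does not cover every manifest slice", call. = FALSE)
    }
    features <- features[match(manifest$slice_id, features$slice_id), ,
                         drop = FALSE]
    if (!include_topology) {
      keep <- !startsWith(names(features), "topo_")
      features <- features[, keep, drop = FALSE]
    }
  }

  split <- split_dataset(manifest, ratio = ratio, seed = seed)
  train_man <- manifest[manifest$slice_id %in% split$train_ids, , drop = FALSE]
  train_feat <- features[features$slice_id %in% split$train_ids, ,
                         drop = FALSE]
  test_feat <- features[features$slice_id %in% split$test_ids, , drop = FALSE]

  # slice-level diagnostic graph: TRAINING labels only
  sg <- build_slice_graph(train_man)
  sum_clean <- topo_summary(class_subgraph(sg, 0))
  sum_art <- topo_summary(class_subgraph(sg, 1))

  consistency_ok <- NA
  class_means <- NULL
  if (include_topology && all(c("topo_avg_degree", "topo_avg_clustering")
                              %in% names(train_feat))) {
    lab <- train_feat$label
    class_means <- list(
      clean = colMeans(train_feat[lab == 0L,
                                  c("topo_avg_degree", "topo_avg_clustering"),
                                  drop = FALSE]),
      artifact = colMeans(train_feat[lab == 1L,
                                     c("topo_avg_degree",
                                       "topo_avg_clustering"),
                                     drop = FALSE]))
    consistency_ok <-
      class_means$artifact["topo_avg_degree"] >
      class_means$clean["topo_avg_degree"] &&
      class_means$artifact["topo_avg_clustering"] >
      class_means$clean["topo_avg_clustering"]
    if (!isTRUE(consistency_ok)) {
      warning(paste("consistency check failed: artifact class does not",
                    "exceed clean class in mean pixel-graph average degree",
                    "and clustering"), call. = FALSE)
    }
  }

  model <- train_classifier(train_feat, kind = classifier, seed = seed)
  eval <- evaluate_model(model, test_feat)
  preds <- predict_classifier(model, test_feat)
  preds$label <- as.integer(test_feat$label)

  report <- structure(list(
    config = list(classifier = classifier, radius = params$radius,
                  grey_threshold = params$grey_threshold,
                  metric = params$metric,
                  foreground_min = params$foreground_min,
                  ratio = ratio, seed = seed,
                  include_topology = include_topology,
                  n_slices = nrow(manifest)),
    split = list(n_train = length(split$train_ids),
                 n_test = length(split$test_ids),
                 train_ids = split$train_ids, test_ids = split$test_ids),
    train_topology = list(clean = sum_clean, artifact = sum_art,
                          pixel_class_means = class_means),
    consistency_ok = consistency_ok,
    eval = eval,
    predictions = preds
  ), class = "madm_report")

  if (!is.null(report_path)) {
    write_report(report, report_path)
  }
  report
}

#' Write a pipeline report as JSON
#'
#' @param report A `"madm_report"` from [run_madm_cn()].
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  if (!inherits(report, "madm_report")) {
    stop("`report` must come from run_madm_cn()", call. = FALSE)
  }
  out <- list(
    config = report$config,
    split = report$split[c("n_train", "n_test")],
    train_topology = list(
      clean = topo_summary_as_list(report$train_topology$clean),
      artifact = topo_summary_as_list(report$train_topology$artifact),
      pixel_class_means = lapply(report$train_topology$pixel_class_means,
                                 as.list)),
    consistency_ok = report$consistency_ok,
    eval = unclass(report$eval),
    predictions = report$predictions
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.madm_report <- function(x, ...) {
  cat(sprintf("MADM-CN run: %s, r = %s, t = %s, split %d/%d, seed %s\n",
              x$config$classifier, x$config$radius,
              x$config$grey_threshold, x$split$n_train, x$split$n_test,
              format(x$config$seed)))
  if (!is.na(x$consistency_ok)) {
    cat(sprintf("  class-consistency (artifact denser than clean): %s\n",
                ifelse(isTRUE(x$consistency_ok), "ok", "VIOLATED")))
  }
  print(x$eval)
  invisible(x)
}
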