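#' Physical (intensity) features of a slice
#'
#' A fixed-order vector of six intensity statistics:
#' `mean`, `sd` (sample standard deviation), `skewness` and `kurtosis`
#' (population moment ratios; excess kurtosis; both reported as 0 for a
#' constant image), `entropy` (Shannon entropy in bits of the 256-bin
#' intensity histogram) and `gradient` (mean gradient magnitude from central
#' differences with replicated borders).
#'
#' @param image Numeric matrix with intensities in `[0, 255]`.
#' @return Named numeric vector of length 6, names prefixed `phys_`.
#' @examples
#' physical_features(matrix(100, 8, 8))
#' @export
physical_features <- function(image) {
  check_gray_image(image)
  v <- as.numeric(image)
  m <- mean(v)
  s_pop <- sqrt(mean((v - m)^2))
  skew <- if (s_pop == 0) 0 else mean((v - m)^3) / s_pop^3
  kurt <- if (s_pop == 0) 0 else mean((v - m)^4) / s_pop^4 - 3
  s <- if (length(v) > 1L) stats::sd(v) else 0

  counts <- tabulate(pmin(pmax(round(v), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  p <- p[p > 0]
  entropy <- -sum(p * log2(p))

  h <- nrow(image)
  w <- ncol(image)
  storage.mode(image) <- "double"
  gx <- (image[, pmin(seq_len(w) + 1L, w), drop = FALSE] -
           image[, pmax(seq_len(w) - 1L, 1L), drop = FALSE]) / 2
  gy <- (image[pmin(seq_len(h) + 1L, h), , drop = FALSE] -
           image[pmax(seq_len(h) - 1L, 1L), , drop = FALSE]) / 2
  grad <- mean(sqrt(gx^2 + gy^2))

  c(phys_mean = m, phys_sd = s, phys_skewness = skew, phys_kurtosis = kurt,
    phys_entropy = entropy, phys_gradient = grad)
}

#' Topological features of a slice's pixel graph
#'
#' Builds the pixel-level network and returns `[average_degree,
#' average_clustering, n_edges]` in fixed order; the average path length can
#' be appended behind a flag (all-pairs BFS is costly on 16k-vertex graphs).
#' A single-pixel image yields all zeros.
#'
#' @param image Numeric matrix with intensities in `[0, 255]`.
#' @param params A [graph_params()] object.
#' @param path_length Append `topo_apl`. Default `FALSE`.
#' @return Named numeric vector, names prefixed `topo_`.
#' @export
topological_features <- function(image, params = graph_params(),
                                 path_length = FALSE) {
  check_gray_image(image)
  if (length(image) == 1L) {
    out <- c(topo_avg_degree = 0, topo_avg_clustering = 0, topo_n_edges = 0)
    if (path_length) out <- c(out, topo_apl = NA_real_)
    return(out)
  }
  g <- build_pixel_graph(image, params)
  out <- c(topo_avg_degree = average_degree(g),
           topo_avg_clustering = average_clustering(g),
           topo_n_edges = as.numeric(igraph::ecount(g)))
  if (path_length) {
    apl <- tryCatch(average_path_length(g), error = function(e) NA_real_)
    out <- c(out, topo_apl = apl)
  }
  out
}

#' Extract the per-slice feature table for a dataset
#'
#' Reads every image in the manifest and computes the physical and (by
#' default) pixel-graph topological features, returning one row per slice in
#' manifest order.
#'
#' @param manifest Manifest `data.frame` (see [read_manifest()]).
#' @param params A [graph_params()] object for the pixel graphs.
#' @param include_topology Compute topological features. Default `TRUE`.
#' @param path_length Also compute pixel-graph average path length. Default
#'   `FALSE`.
#' @param base_dir Optional directory against which relative `image_path`
#'   entries are resolved.
#' @return `data.frame` with columns `slice_id`, `label` (= `quality_label`)
#'   and the feature columns (`phys_*`, `topo_*`).
#' @export
extract_features <- function(manifest, params = graph_params(),
                             include_topology = TRUE, path_length = FALSE,
                             base_dir = NULL) {
  check_manifest(manifest)
  paths <- manifest$image_path
  if (!is.null(base_dir)) {
    rel <- !grepl("^(/|[A-Za-z]:)", paths)
    paths[rel] <- file.path(base_dir, paths[rel])
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_gray_image(paths[i])
    f <- physical_features(img)
    if (include_topology) {
      f <- c(f, topological_features(img, params, path_length = path_length))
    }
    f
  })
  feats <- do.call(rbind, rows)
  out <- data.frame(slice_id = manifest$slice_id,
                    label = as.integer(manifest$quality_label),
                    feats, stringsAsFactors = FALSE, row.names = NULL)
  out
}
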