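#' Build the slice-level network
#'
#' Vertices are slices; an undirected edge joins two distinct slices exactly
#' when they share both the anatomical region label and the quality label.
#' The edge relation is transitive within a (region, label) group, so every
#' connected component is a complete graph (clique); slices matching no other
#' slice remain isolated vertices.
#'
#' Because the edge rule uses quality labels, slice graphs must be built from
#' training labels only: they are a class-consistency diagnostic, never a
#' test-time feature (using them at test time would leak the label being
#' predicted).
#'
#' @param records A `data.frame` with columns `slice_id` (unique),
#'   `region_label` (positive integer) and `quality_label` (0 or 1), e.g. a
#'   manifest from [generate_dataset()] or [read_manifest()].
#' @return An [igraph::igraph] graph with vertex attributes `name`
#'   (= `slice_id`), `region_label` and `quality_label`.
#' @examples
#' recs <- data.frame(slice_id = letters[1:6],
#'                    region_label = c(1, 2, 1, 3, 2, 1),
#'                    quality_label = c(0, 1, 0, 1, 1, 0))
#' g <- build_slice_graph(recs)
#' igraph::ecount(g)  # 4: a-c, a-f, c-f, b-e
#' @export
build_slice_graph <- function(records) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data.frame", call. = FALSE)
  }
  needed <- c("slice_id", "region_label", "quality_label")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) {
    stop(sprintf("`records` is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ids <- as.character(records$slice_id)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop(sprintf("duplicate slice_id '%s' in records", dup), call. = FALSE)
  }
  if (!all(records$quality_label %in% c(0, 1))) {
    stop("`quality_label` must be 0 or 1 for every record", call. = FALSE)
  }

  n <- length(ids)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$region_label <- as.integer(records$region_label)
  igraph::V(g)$quality_label <- as.integer(records$quality_label)

  if (n >= 2L) {
    key <- paste(records$region_label, records$quality_label, sep = "\r")
    groups <- split(seq_len(n), key)
    pairs <- lapply(groups, function(m) {
      if (length(m) < 2L) return(NULL)
      utils::combn(m, 2L)
    })
    pairs <- pairs[!vapply(pairs, is.null, logical(1))]
    if (length(pairs) > 0L) {
      g <- igraph::add_edges(g, do.call(cbind, pairs))
    }
  }
  g
}

#' Induced subgraph of one quality class
#'
#' Restricts a slice-level graph to the slices carrying the given quality
#' label, keeping all edges among them — the per-class view used for the
#' class-wise topological summaries.
#'
#' @param graph A slice graph from [build_slice_graph()].
#' @param quality_label 0 (clean) or 1 (artifact).
#' @return The induced [igraph::igraph] subgraph.
#' @export
class_subgraph <- function(graph, quality_label) {
  if (!quality_label %in% c(0, 1)) {
    stop("`quality_label` must be 0 or 1", call. = FALSE)
  }
  keep <- which(igraph::V(graph)$quality_label == quality_label)
  igraph::induced_subgraph(graph, keep)
}
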