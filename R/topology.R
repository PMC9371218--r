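#' @name topology
#' @title Topological properties of undirected, unweighted graphs
#' @description
#' The detector characterizes a graph by a small set of classical network
#' statistics: vertex degree, average degree (handshake convention
#' `2|E|/|V|`), degree distribution, the local clustering coefficient
#' `C_i = 2 T_i / (k_i (k_i - 1))` (with `T_i` the number of edges among the
#' `k_i` neighbours of vertex `i`, and `C_i := 0` when `k_i <= 1`), its
#' average over vertices, and the average shortest-path length over connected
#' vertex pairs. All functions operate on [igraph::igraph] objects as produced
#' by [build_pixel_graph()] or [build_slice_graph()].
NULL

check_nonempty_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object", call. = FALSE)
  }
  if (igraph::vcount(graph) == 0L) {
    stop("undefined on an empty graph", call. = FALSE)
  }
  invisible(graph)
}

resolve_vertex <- function(graph, vertex) {
  if (is.character(vertex)) {
    pos <- match(vertex, igraph::V(graph)$name)
    if (is.na(pos)) {
      stop(sprintf("unknown vertex '%s'", vertex), call. = FALSE)
    }
    return(pos)
  }
  if (!is.numeric(vertex) || length(vertex) != 1L || is.na(vertex) ||
      vertex < 1 || vertex > igraph::vcount(graph)) {
    stop("unknown vertex", call. = FALSE)
  }
  as.integer(vertex)
}

#' Degree of one vertex
#'
#' @param graph An undirected [igraph::igraph] graph.
#' @param vertex Vertex name (character) or 1-based index.
#' @return Integer count of incident edges.
#' @rdname topology
#' @export
vertex_degree <- function(graph, vertex) {
  check_nonempty_graph(graph)
  v <- resolve_vertex(graph, vertex)
  as.integer(igraph::degree(graph, v))
}

#' Average degree, `2|E|/|V|`
#'
#' @rdname topology
#' @export
average_degree <- function(graph) {
  check_nonempty_graph(graph)
  2 * igraph::ecount(graph) / igraph::vcount(graph)
}

#' Degree distribution `P(k)`
#'
#' @return Named numeric vector: `P(k)` indexed by degree `k`; sums to 1.
#' @rdname topology
#' @export
degree_distribution <- function(graph) {
  check_nonempty_graph(graph)
  k <- igraph::degree(graph)
  tab <- table(k)
  p <- as.numeric(tab) / igraph::vcount(graph)
  names(p) <- names(tab)
  p
}

#' Local clustering coefficient of one vertex
#'
#' `C_i = 2 T_i / (k_i (k_i - 1))`, the fraction of realized edges among the
#' neighbours of `i`; 0 by convention for `k_i <= 1`.
#'
#' @rdname topology
#' @export
clustering_coefficient <- function(graph, vertex) {
  check_nonempty_graph(graph)
  v <- resolve_vertex(graph, vertex)
  k <- unname(igraph::degree(graph, v))
  if (k <= 1) return(0)
  nb <- igraph::neighbors(graph, v)
  t_i <- igraph::ecount(igraph::induced_subgraph(graph, nb))
  unname(2 * t_i / (k * (k - 1)))
}

# Vectorized C_i for all vertices via per-vertex triangle counts.
local_clustering <- function(graph) {
  k <- igraph::degree(graph)
  tri <- igraph::count_triangles(graph)
  ifelse(k <= 1, 0, 2 * tri / (k * (k - 1)))
}

#' Average clustering coefficient
#'
#' Arithmetic mean of `C_i` over vertices. By default vertices with `k <= 1`
#' contribute 0 to the mean; `include_low_degree = FALSE` excludes them.
#'
#' @param include_low_degree Include vertices of degree `<= 1` (as zeros) in
#'   the average. Default `TRUE`.
#' @rdname topology
#' @export
average_clustering <- function(graph, include_low_degree = TRUE) {
  check_nonempty_graph(graph)
  ci <- local_clustering(graph)
  if (!include_low_degree) {
    k <- igraph::degree(graph)
    ci <- ci[k > 1]
    if (length(ci) == 0L) return(0)
  }
  mean(ci)
}

#' Average shortest-path length
#'
#' Mean shortest-path length over all unordered *connected* vertex pairs;
#' disconnected pairs are excluded. Errors when the graph has no connected
#' pair (no edges).
#'
#' @rdname topology
#' @export
average_path_length <- function(graph) {
  check_nonempty_graph(graph)
  if (igraph::ecount(graph) == 0L) {
    stop("average path length undefined: no connected vertex pair",
         call. = FALSE)
  }
  igraph::mean_distance(graph, directed = FALSE, unconnected = TRUE)
}

#' Summarize a graph's topology
#'
#' Aggregates vertex/edge counts, average degree, average clustering
#' coefficient, average path length and the degree distribution into one
#' record. When the average path length is undefined (edgeless graph) it is
#' reported as `NA`.
#'
#' @param graph An undirected [igraph::igraph] graph with at least 1 vertex.
#' @param path_length Compute the average path length (all-pairs BFS; costly
#'   on large pixel graphs). Default `TRUE`.
#' @return A list of class `"topo_summary"` with fields `n_vertices`,
#'   `n_edges`, `average_degree`, `average_clustering`,
#'   `average_path_length`, `degree_distribution`.
#' @examples
#' g <- igraph::make_full_graph(4)
#' topo_summary(g)
#' @export
topo_summary <- function(graph, path_length = TRUE) {
  check_nonempty_graph(graph)
  apl <- if (path_length) {
    tryCatch(average_path_length(graph), error = function(e) NA_real_)
  } else {
    NA_real_
  }
  structure(list(
    n_vertices = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    average_degree = average_degree(graph),
    average_clustering = average_clustering(graph),
    average_path_length = apl,
    degree_distribution = degree_distribution(graph)
  ), class = "topo_summary")
}

#' @export
print.topo_summary <- function(x, ...) {
  cat("Graph topology summary\n")
  cat(sprintf("  vertices (N):              %d\n", x$n_vertices))
  cat(sprintf("  edges (|E|):               %d\n", x$n_edges))
  cat(sprintf("  average degree:            %.4f\n", x$average_degree))
  cat(sprintf("  average clustering coef.:  %.4f\n", x$average_clustering))
  cat(sprintf("  average path length:       %s\n",
              ifelse(is.na(x$average_path_length), "undefined",
                     sprintf("%.4f", x$average_path_length))))
  invisible(x)
}
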