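#' Pixel-graph construction parameters
#'
#' Bundles the tunable knobs of the pixel-level network construction: the
#' spatial radius gate, the grey-difference gate, the distance metric, and an
#' optional foreground mask.
#'
#' @param radius Positive spatial radius `r` in pixel units; two pixels can be
#'   linked only if their distance is `<= r` (inclusive). Default 3, the
#'   working radius of the detector.
#' @param grey_threshold Non-negative integer `t` on the 0--255 intensity
#'   scale; an edge additionally requires `|I_i - I_j| <= t`. Default 10.
#' @param metric Distance metric on integer pixel coordinates: `"euclidean"`
#'   (default) or `"chebyshev"`.
#' @param foreground_min Optional minimum intensity for a pixel to become a
#'   vertex; `NULL` (default) makes every pixel a vertex. Masking near-zero
#'   air pixels is useful because they dominate head CT slices.
#' @return A list of class `"graph_params"`.
#' @export
graph_params <- function(radius = 3, grey_threshold = 10,
                         metric = c("euclidean", "chebyshev"),
                         foreground_min = NULL) {
  metric <- match.arg(metric)
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(grey_threshold) || length(grey_threshold) != 1L ||
      is.na(grey_threshold) || grey_threshold < 0) {
    stop("`grey_threshold` must be a single non-negative number",
         call. = FALSE)
  }
  if (!is.null(foreground_min)) {
    foreground_min <- as.numeric(foreground_min)
    stopifnot(length(foreground_min) == 1L, !is.na(foreground_min))
  }
  structure(list(radius = radius, grey_threshold = grey_threshold,
                 metric = metric, foreground_min = foreground_min),
            class = "graph_params")
}

#' Integer pixel offsets within a radius
#'
#' Enumerates every nonzero integer offset `(drow, dcol)` whose length under
#' the chosen metric does not exceed `radius`. The set is symmetric under
#' negation. For `radius = 3` (euclidean) there are 28 offsets, so 28 is the
#' maximum attainable pixel degree at that radius.
#'
#' @param radius Positive radius in pixel units.
#' @param metric `"euclidean"` or `"chebyshev"`.
#' @return An integer matrix with columns `drow`, `dcol`, one offset per row.
#' @examples
#' nrow(neighborhood_offsets(3))  # 28
#' @export
neighborhood_offsets <- function(radius,
                                 metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  rmax <- floor(radius)
  d <- expand.grid(drow = -rmax:rmax, dcol = -rmax:rmax)
  d <- d[d$drow != 0 | d$dcol != 0, , drop = FALSE]
  keep <- if (metric == "euclidean") {
    sqrt(d$drow^2 + d$dcol^2) <= radius
  } else {
    pmax(abs(d$drow), abs(d$dcol)) <= radius
  }
  m <- as.matrix(d[keep, , drop = FALSE])
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Map a grayscale slice to a pixel-level complex network
#'
#' Vertices are pixels (all of them, or only those at or above
#' `foreground_min`); an undirected, unweighted edge joins two distinct pixels
#' exactly when their spatial distance is at most `radius` *and* their
#' grey-level difference is at most `grey_threshold`. The result does not
#' depend on any pixel visitation order.
#'
#' Vertex names are flattened row-major pixel indices
#' (`(row - 1) * width + col`, 1-based); vertex attributes `row`, `col`,
#' `intensity` carry the original coordinates, and the construction
#' parameters are stored as graph attributes.
#'
#' @param image Numeric matrix with intensities in `[0, 255]`.
#' @param params A [graph_params()] object.
#' @return An [igraph::igraph] graph.
#' @examples
#' g <- build_pixel_graph(matrix(100, 2, 2),
#'                        graph_params(radius = 3, grey_threshold = 255))
#' igraph::ecount(g)  # K4: 6 edges
#' @export
build_pixel_graph <- function(image, params = graph_params()) {
  check_gray_image(image)
  if (!inherits(params, "graph_params")) {
    stop("`params` must be created with graph_params()", call. = FALSE)
  }
  h <- nrow(image)
  w <- ncol(image)
  storage.mode(image) <- "double"

  offs <- neighborhood_offsets(params$radius, params$metric)
  # one representative per unordered offset pair
  half <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0), ,
               drop = FALSE]

  idx <- matrix(seq_len(h * w), h, w, byrow = TRUE)  # row-major pixel ids
  fg <- if (is.null(params$foreground_min)) {
    matrix(TRUE, h, w)
  } else {
    image >= params$foreground_min
  }

  from <- vector("list", nrow(half))
  to <- vector("list", nrow(half))
  for (k in seq_len(nrow(half))) {
    dr <- half[k, 1]
    dc <- half[k, 2]
    rlo <- max(1L, 1L - dr)
    rhi <- min(h, h - dr)
    clo <- max(1L, 1L - dc)
    chi <- min(w, w - dc)
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi
    c1 <- clo:chi
    a <- image[r1, c1, drop = FALSE]
    b <- image[r1 + dr, c1 + dc, drop = FALSE]
    ok <- abs(a - b) <= params$grey_threshold &
      fg[r1, c1, drop = FALSE] & fg[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(ok)) next
    from[[k]] <- idx[r1, c1, drop = FALSE][ok]
    to[[k]] <- idx[r1 + dr, c1 + dc, drop = FALSE][ok]
  }
  from <- unlist(from, use.names = FALSE)
  to <- unlist(to, use.names = FALSE)

  vids <- sort(idx[fg])
  if (length(vids) == 0L) {
    stop("no vertices: every pixel falls below `foreground_min`",
         call. = FALSE)
  }
  lookup <- integer(h * w)
  lookup[vids] <- seq_along(vids)

  g <- igraph::make_empty_graph(n = length(vids), directed = FALSE)
  if (length(from) > 0L) {
    g <- igraph::add_edges(g, rbind(lookup[from], lookup[to]))
  }
  rows <- ((vids - 1L) %/% w) + 1L
  cols <- ((vids - 1L) %% w) + 1L
  igraph::V(g)$name <- as.character(vids)
  igraph::V(g)$row <- rows
  igraph::V(g)$col <- cols
  igraph::V(g)$intensity <- image[cbind(rows, cols)]
  g <- igraph::set_graph_attr(g, "radius", params$radius)
  g <- igraph::set_graph_attr(g, "grey_threshold", params$grey_threshold)
  g <- igraph::set_graph_attr(g, "metric", params$metric)
  g <- igraph::set_graph_attr(g, "height", h)
  g <- igraph::set_graph_attr(g, "width", w)
  g
}
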