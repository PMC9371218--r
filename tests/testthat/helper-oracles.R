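# Independent brute-force oracles, written in plain R against edge lists so
# they share no code path with the package implementation.

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Naive O(n^2) pixel-graph oracle: double loop over all pixel pairs applying
# the radius and grey-difference gates. Returns sorted edge keys over
# row-major pixel ids.
ref_pixel_edge_keys <- function(image, radius, threshold,
                                metric = "euclidean",
                                foreground_min = NULL) {
  h <- nrow(image)
  w <- ncol(image)
  ids <- integer(0)
  rows <- integer(0)
  cols <- integer(0)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (is.null(foreground_min) || image[r, c] >= foreground_min) {
        ids <- c(ids, (r - 1L) * w + c)
        rows <- c(rows, r)
        cols <- c(cols, c)
      }
    }
  }
  keys <- character(0)
  n <- length(ids)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- if (metric == "euclidean") {
          sqrt((rows[i] - rows[j])^2 + (cols[i] - cols[j])^2)
        } else {
          max(abs(rows[i] - rows[j]), abs(cols[i] - cols[j]))
        }
        if (d <= radius &&
            abs(image[rows[i], cols[i]] - image[rows[j], cols[j]]) <=
              threshold) {
          keys <- c(keys, edge_key(ids[i], ids[j]))
        }
      }
    }
  }
  sort(keys)
}

pixel_graph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  sort(edge_key(as.integer(el[, 1]), as.integer(el[, 2])))
}

# Plain-R adjacency structures from an integer edge matrix (2 columns, 1-based
# vertex indices) on n vertices.
ref_adjacency <- function(n, edges) {
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  if (length(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]
      b <- edges[e, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

ref_degrees <- function(n, edges) {
  vapply(ref_adjacency(n, edges), length, integer(1))
}

# Exhaustive neighbour-pair scan: C_i = 2 T_i / (k_i (k_i - 1)).
ref_local_clustering <- function(n, edges) {
  adj <- ref_adjacency(n, edges)
  has_edge <- new.env(hash = TRUE)
  if (length(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      assign(edge_key(edges[e, 1], edges[e, 2]), TRUE, envir = has_edge)
    }
  }
  vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k <= 1L) return(0)
    t_i <- 0L
    for (i in 1:(k - 1L)) {
      for (j in (i + 1L):k) {
        if (exists(edge_key(nb[i], nb[j]), envir = has_edge)) t_i <- t_i + 1L
      }
    }
    2 * t_i / (k * (k - 1))
  }, numeric(1))
}

# Breadth-first search average shortest-path length over unordered connected
# vertex pairs; NA when no pair is connected.
ref_apl <- function(n, edges) {
  adj <- ref_adjacency(n, edges)
  total <- 0
  pairs <- 0L
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1]
      queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + 1L
          queue <- c(queue, u)
        }
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) > s)
    total <- total + sum(dist[reach])
    pairs <- pairs + length(reach)
  }
  if (pairs == 0L) NA_real_ else total / pairs
}

# Random simple graph as a plain edge matrix (no igraph involved).
rand_edges <- function(n, p) {
  edges <- NULL
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (stats::runif(1) < p) edges <- rbind(edges, c(i, j))
      }
    }
  }
  if (is.null(edges)) matrix(integer(0), 0, 2) else edges
}

edges_to_igraph <- function(n, edges) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n))
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  g
}

# Random slice manifest (records only, no images).
rand_records <- function(n, n_regions) {
  data.frame(slice_id = sprintf("s%03d", seq_len(n)),
             region_label = sample.int(n_regions, n, replace = TRUE),
             quality_label = sample(c(0L, 1L), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

table1_records <- function() {
  data.frame(slice_id = c("a", "b", "c", "d", "e", "f"),
             region_label = c(1L, 2L, 1L, 3L, 2L, 1L),
             quality_label = c(0L, 1L, 0L, 1L, 1L, 0L),
             stringsAsFactors = FALSE)
}

slice_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
}

rand_gray_image <- function(h, w, levels = 0:255) {
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}
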