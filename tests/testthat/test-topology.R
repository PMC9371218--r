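test_that("closed-form topology values hold on canonical graphs", {
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- as.character(1:4)
  s <- topo_summary(k4)
  expect_equal(s$n_vertices, 4)
  expect_equal(s$n_edges, 6)
  expect_equal(s$average_degree, 3)
  expect_equal(s$average_clustering, 1)
  expect_equal(s$average_path_length, 1)
  expect_equal(s$degree_distribution, c("3" = 1))
  expect_equal(vertex_degree(k4, 1), 3)

  # complete graphs: avg degree n - 1, clustering 1
  for (n in c(3, 5, 8)) {
    kn <- igraph::make_full_graph(n)
    expect_equal(average_degree(kn), n - 1)
    expect_equal(average_clustering(kn), 1)
    expect_equal(average_path_length(kn), 1)
  }

  # path a-b-c: middle vertex clustering 0, APL (1 + 1 + 2)/3
  p3 <- edges_to_igraph(3, rbind(c(1, 2), c(2, 3)))
  expect_equal(clustering_coefficient(p3, 2), 0)
  expect_equal(average_path_length(p3), 4 / 3)

  # triangle: clustering 1 everywhere
  tri <- edges_to_igraph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(clustering_coefficient(tri, 1), 1)

  # star S3: P(3) = 1/4, P(1) = 3/4
  star <- edges_to_igraph(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(degree_distribution(star), c("1" = 0.75, "3" = 0.25))
})

test_that("the worked six-slice graph summarizes correctly", {
  g <- build_slice_graph(table1_records())
  expect_equal(vertex_degree(g, "a"), 2)
  expect_equal(vertex_degree(g, "d"), 0)
  s <- topo_summary(g)
  expect_equal(s$n_vertices, 6)
  expect_equal(s$n_edges, 4)
  expect_equal(s$average_degree, 8 / 6)
  expect_equal(s$average_clustering, 0.5)
  expect_equal(s$average_path_length, 1)  # components are cliques; d isolated
  expect_equal(s$degree_distribution,
               c("0" = 1 / 6, "1" = 1 / 3, "2" = 1 / 2))
})

test_that("degenerate graphs are handled by convention", {
  lonely <- edges_to_igraph(2, matrix(integer(0), 0, 2))
  expect_equal(average_degree(lonely), 0)
  expect_equal(average_clustering(lonely), 0)
  expect_error(average_path_length(lonely), "no connected")
  s <- topo_summary(lonely)
  expect_true(is.na(s$average_path_length))
  expect_equal(s$n_edges, 0)

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_error(average_degree(empty), "empty")
  expect_error(topo_summary(empty), "empty")
  expect_error(vertex_degree(lonely, "zz"), "unknown vertex")
})

test_that("topology matches brute-force oracles on random graphs", {
  set.seed(20)
  for (rep in 1:40) {
    n <- sample(2:20, 1)
    edges <- rand_edges(n, stats::runif(1, 0.05, 0.9))
    g <- edges_to_igraph(n, edges)

    # degrees + handshake
    deg <- vapply(seq_len(n), function(v) vertex_degree(g, v), integer(1))
    expect_identical(deg, ref_degrees(n, edges))
    expect_equal(sum(deg), 2 * igraph::ecount(g))
    expect_equal(average_degree(g), 2 * nrow(edges) / n)

    # per-vertex clustering: exhaustive neighbour-pair scan
    ci_ref <- ref_local_clustering(n, edges)
    ci <- vapply(seq_len(n), function(v) clustering_coefficient(g, v),
                 numeric(1))
    expect_equal(ci, ci_ref)
    expect_true(all(ci >= 0 & ci <= 1))
    expect_equal(average_clustering(g), mean(ci_ref))

    # degree distribution sums to 1
    expect_equal(sum(degree_distribution(g)), 1, tolerance = 1e-12)

    # average path length: BFS oracle over connected unordered pairs
    apl_ref <- ref_apl(n, edges)
    if (is.na(apl_ref)) {
      expect_error(average_path_length(g))
    } else {
      expect_equal(average_path_length(g), apl_ref)
    }
  }
})

test_that("average clustering agrees with an independent library formula", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    g <- edges_to_igraph(n, rand_edges(n, 0.3))
    expect_equal(average_clustering(g),
                 igraph::transitivity(g, type = "localaverage",
                                      isolates = "zero"))
  }
})

test_that("low-degree vertices can be excluded from the clustering average", {
  # triangle plus pendant vertex: include -> 3/4, exclude -> 1
  g <- edges_to_igraph(4, rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  expect_equal(average_clustering(g), mean(c(1, 1, 1 / 3, 0)))
  k <- igraph::degree(g)
  expect_equal(average_clustering(g, include_low_degree = FALSE),
               mean(c(1, 1, 1 / 3)))
})
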