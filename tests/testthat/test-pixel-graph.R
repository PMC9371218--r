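test_that("neighborhood offsets enumerate the radius ball", {
  cases <- list(list(r = 1, metric = "euclidean", n = 4),
                list(r = 3, metric = "euclidean", n = 28),
                list(r = 1, metric = "chebyshev", n = 8),
                list(r = 2, metric = "euclidean", n = 12),
                list(r = 2, metric = "chebyshev", n = 24))
  for (cs in cases) {
    offs <- neighborhood_offsets(cs$r, cs$metric)
    expect_equal(nrow(offs), cs$n,
                 info = sprintf("r=%s %s", cs$r, cs$metric))
    # symmetric under negation, no zero offset
    keys <- paste(offs[, 1], offs[, 2])
    expect_setequal(keys, paste(-offs[, 1], -offs[, 2]))
    expect_false("0 0" %in% keys)
  }
  expect_error(neighborhood_offsets(0), "positive")
})

test_that("worked small pixel graphs match hand-derived structure", {
  # 2x2 constant image, generous gates -> K4
  g <- build_pixel_graph(matrix(7, 2, 2),
                         graph_params(radius = 3, grey_threshold = 255))
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 6)

  # 3x3 intensities 0..8 row-major, r = 1 -> 4-neighbour grid, 12 edges
  img <- matrix(0:8, 3, 3, byrow = TRUE)
  g <- build_pixel_graph(img, graph_params(radius = 1, grey_threshold = 255))
  expect_equal(igraph::ecount(g), 12)
  expect_equal(sort(unique(igraph::degree(g))), c(2, 3, 4))
})

test_that("interior degree on a constant image saturates the offset count", {
  img <- matrix(42, 12, 12)
  g <- build_pixel_graph(img, graph_params(radius = 3, grey_threshold = 0))
  deg <- igraph::degree(g)
  rows <- igraph::V(g)$row
  cols <- igraph::V(g)$col
  interior <- rows >= 4 & rows <= 9 & cols >= 4 & cols <= 9
  expect_true(all(deg[interior] == 28))
  expect_true(all(deg <= 28))
})

test_that("pixel graph equals the naive all-pairs oracle", {
  set.seed(421)
  cases <- expand.grid(r = c(1, 2, 3), t = c(0, 10, 40),
                       metric = c("euclidean", "chebyshev"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    h <- sample(2:10, 1)
    w <- sample(2:10, 1)
    img <- rand_gray_image(h, w, levels = 0:60)
    p <- graph_params(radius = cases$r[i], grey_threshold = cases$t[i],
                      metric = cases$metric[i])
    g <- build_pixel_graph(img, p)
    expect_identical(pixel_graph_edge_keys(g),
                     ref_pixel_edge_keys(img, cases$r[i], cases$t[i],
                                         cases$metric[i]),
                     info = sprintf("case %d", i))
    # simple graph: no loops, no multi-edges
    expect_false(igraph::any_loop(g))
    expect_false(igraph::any_multiple(g))
  }
})

test_that("foreground masking drops sub-threshold vertices", {
  img <- matrix(c(0, 0, 100, 100), 2, 2)
  g <- build_pixel_graph(img, graph_params(radius = 3, grey_threshold = 255,
                                           foreground_min = 50))
  expect_equal(igraph::vcount(g), 2)
  expect_equal(igraph::ecount(g), 1)
  expect_identical(pixel_graph_edge_keys(g),
                   ref_pixel_edge_keys(img, 3, 255, "euclidean",
                                       foreground_min = 50))
})

test_that("edge set grows monotonically in radius and grey threshold", {
  set.seed(99)
  for (rep in 1:5) {
    img <- rand_gray_image(8, 8, levels = 0:80)
    e_small <- pixel_graph_edge_keys(
      build_pixel_graph(img, graph_params(radius = 2, grey_threshold = 15)))
    e_big_t <- pixel_graph_edge_keys(
      build_pixel_graph(img, graph_params(radius = 2, grey_threshold = 40)))
    e_big_r <- pixel_graph_edge_keys(
      build_pixel_graph(img, graph_params(radius = 3, grey_threshold = 15)))
    expect_true(all(e_small %in% e_big_t))
    expect_true(all(e_small %in% e_big_r))
  }
})

test_that("pixel graph construction validates inputs", {
  expect_error(build_pixel_graph(matrix(300, 2, 2)), "\\[0, 255\\]")
  expect_error(build_pixel_graph(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(build_pixel_graph(matrix(1, 2, 2), params = list()),
               "graph_params")
})
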