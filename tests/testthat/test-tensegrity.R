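test_that("six-strut builder emits 12 nodes, 6 bars, 24 tendons on a sphere", {
  tg <- build_icosahedron_tensegrity(1)
  expect_equal(nrow(tg$nodes), 12L)
  expect_equal(nrow(tg$bars), 6L)
  expect_equal(nrow(tg$tendons), 24L)
  # every node at distance 1 from the center (relative tol 1e-12)
  expect_equal(sqrt(rowSums(tg$nodes^2)), rep(1, 12), tolerance = 1e-12)
  # edge set has 30 distinct members, none repeated between bars/tendons
  edges <- rbind(tg$bars, tg$tendons)
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_equal(length(unique(key)), 30L)
})

test_that("per-node degrees from brute-force adjacency: 1 bar, 4 tendons", {
  for (r in c(1, 3.7e-6)) {
    tg <- build_icosahedron_tensegrity(r)
    bar_deg <- tabulate(as.vector(tg$bars), 12)
    ten_deg <- tabulate(as.vector(tg$tendons), 12)
    expect_equal(bar_deg, rep(1L, 12))
    expect_equal(ten_deg, rep(4L, 12))
    # bars vertex-disjoint: no node appears twice among bar endpoints
    expect_false(anyDuplicated(as.vector(tg$bars)) > 0)
  }
})

test_that("graph is isomorphic to the canonical six-strut tensegrity", {
  skip_if_not_installed("igraph")
  # canonical reference: hard-coded bar pairs and tendon list on vertex
  # family (0, +-1, +-c), (+-1, +-c, 0), (+-c, 0, +-1)
  ref_bars <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(9, 10), c(11, 12))
  g_of <- function(bars, tendons) {
    el <- rbind(bars, tendons)
    igraph::graph_from_edgelist(el, directed = FALSE)
  }
  tg <- build_icosahedron_tensegrity(2.5, center = c(1, 2, 3),
                                     shape_transform = diag(c(1, 2, 0.5)))
  g <- g_of(tg$bars, tg$tendons)
  ref <- g_of(ref_bars, build_icosahedron_tensegrity(1)$tendons)
  ecol <- c(rep(1L, 6), rep(2L, 24))
  expect_true(igraph::isomorphic(
    g, ref, method = "vf2", edge.color1 = ecol, edge.color2 = ecol))
})

test_that("shape transform is applied and singular transforms are rejected", {
  A <- diag(c(2, 1, 0.5))
  tg <- build_icosahedron_tensegrity(1, shape_transform = A)
  tg0 <- build_icosahedron_tensegrity(1)
  expect_equal(tg$nodes, t(A %*% t(tg0$nodes)))
  expect_error(build_icosahedron_tensegrity(1,
    shape_transform = matrix(0, 3, 3)), "singular")
  expect_error(build_icosahedron_tensegrity(-1), "positive")
})
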