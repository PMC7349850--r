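uniform_graph <- function(n, w) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}

test_that("strength is the row sum, graph strength the node average", {
  s <- strength(uniform_graph(3, 0.5))
  expect_equal(s$node, rep(1, 3))
  expect_equal(s$graph, 1)
  expect_equal(strength(uniform_graph(5, 0))$graph, 0)
  expect_equal(strength(uniform_graph(9, 0.7))$node, rep(8 * 0.7, 9))
  asym <- matrix(c(0, 1, 0.5, 0), 2)
  expect_error(strength(asym), "not symmetric")
})

test_that("Onnela clustering matches closed forms on canonical graphs", {
  cc <- clustering_coefficient(uniform_graph(4, 0.5))
  expect_equal(cc$node, rep(0.5, 4))
  expect_equal(cc$graph, 0.5)
  open_tri <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3)
  expect_equal(clustering_coefficient(open_tri)$node, rep(0, 3))
  over <- uniform_graph(3, 1.5)
  expect_error(clustering_coefficient(over), "above 1")
  # isolated node contributes 0 without poisoning the graph average
  w <- uniform_graph(4, 0.6)
  w[4, ] <- w[, 4] <- 0
  cc2 <- clustering_coefficient(w)
  expect_equal(cc2$node[4], 0)
  expect_equal(cc2$node[1], 0.6)
})

test_that("shortest paths use 1/w lengths with fractional tie counting", {
  # 3-node path with unit weights: d(1,3) = 2 through the middle
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  sp <- shortest_paths(w)
  expect_equal(sp$distance[1, 3], 2)
  expect_equal(sp$sigma[1, 3], 1)
  # complete uniform graph: the direct edge is always minimal
  wu <- uniform_graph(5, 0.4)
  spu <- shortest_paths(wu)
  expect_true(all(spu$distance[upper.tri(spu$distance)] == 1 / 0.4))
  # disconnected pair: infinite distance, zero path count
  wd <- matrix(0, 4, 4)
  wd[1, 2] <- wd[2, 1] <- 0.5
  spd <- shortest_paths(wd)
  expect_equal(spd$distance[1, 3], Inf)
  expect_equal(spd$sigma[1, 3], 0)
  # two equal-length parallel routes are both counted
  wp <- matrix(0, 4, 4)
  wp[1, 2] <- wp[2, 1] <- 1
  wp[2, 4] <- wp[4, 2] <- 1
  wp[1, 3] <- wp[3, 1] <- 1
  wp[3, 4] <- wp[4, 3] <- 1
  spp <- shortest_paths(wp)
  expect_equal(spp$sigma[1, 4], 2)
})

test_that("betweenness matches canonical closed forms", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  bc <- betweenness_centrality(w)
  expect_equal(bc$node, c(0, 1, 0))
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  bs <- betweenness_centrality(star)
  expect_equal(bs$node, c(1, 0, 0, 0))
  expect_equal(betweenness_centrality(uniform_graph(6, 0.3))$node,
               rep(0, 6))
  expect_error(betweenness_centrality(uniform_graph(2, 0.5)), "3 nodes")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:7, 1)
    w <- random_weight_graph(n, density = runif(1, 0.4, 1))
    expect_equal(strength(w)$node, brute_strength(w)$node,
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(w)$node, brute_clustering(w)$node,
                 tolerance = 1e-12)
    sp <- shortest_paths(w)
    bsp <- brute_shortest_paths(w)
    expect_equal(sp$distance, bsp$distance, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(betweenness_centrality(w)$node, brute_betweenness(w)$node,
                 tolerance = 1e-12)
  }
})

test_that("metrics agree with igraph on weighted random graphs", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    w <- random_weight_graph(n, density = 0.9)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(strength(w)$node, igraph::strength(g), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # igraph counts unordered pairs; the ordered-pair normalisation used
    # here is 2x / ((N-1)(N-2))
    ig_bc <- igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(betweenness_centrality(w)$node,
                 2 * ig_bc / ((n - 1) * (n - 2)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("node relabelling permutes node metrics, not graph averages", {
  set.seed(21)
  w <- random_weight_graph(7)
  p <- sample(7)
  wp <- w[p, p]
  for (f in list(strength, clustering_coefficient, betweenness_centrality)) {
    r <- f(w)
    rp <- f(wp)
    expect_equal(rp$node, r$node[p], tolerance = 1e-12)
    expect_equal(rp$graph, r$graph, tolerance = 1e-12)
  }
})

test_that("uniform weight scaling scales cc and strength, fixes bc", {
  set.seed(22)
  w <- random_weight_graph(6)
  for (c_scale in c(0.2, 0.5, 1)) {
    expect_equal(strength(c_scale * w)$node, c_scale * strength(w)$node,
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(c_scale * w)$node,
                 c_scale * clustering_coefficient(w)$node,
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(c_scale * w)$node,
                 betweenness_centrality(w)$node, tolerance = 1e-12)
  }
})

test_that("summarize_network composes the three metrics per scope", {
  w <- uniform_graph(27, 0.8)
  cm <- eegconnectome:::new_connectivity_matrix(w, paste0("E", 1:27),
                                                "local", 5L)
  ns <- summarize_network(cm)
  expect_equal(ns$cc_graph, 0.8, tolerance = 1e-12)
  expect_equal(ns$strength_graph, 26 * 0.8, tolerance = 1e-12)
  expect_equal(ns$bc_graph, 0)
  expect_equal(ns$scope, "local")
  expect_equal(ns$n_nodes, 27)
  partial <- summarize_network(cm, metrics = "strength")
  expect_true(is.na(partial$cc_graph))
  expect_null(partial$cc_node)
})
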