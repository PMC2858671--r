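test_that("lattices have the exact node and edge counts of a grid", {
  cases <- list(list(c(4, 4), 16, 24),
                list(c(3, 3, 3), 27, 54),
                list(c(10), 10, 9),
                list(c(5, 3), 15, 22))
  for (cs in cases) {
    net <- make_lattice(cs[[1]])
    expect_equal(n_nodes(net), cs[[2]])
    expect_equal(n_edges(net), cs[[3]])
  }
})

test_that("lattices are connected with degree at most 2 per grid dimension", {
  for (lengths in list(c(6, 6), c(4, 3, 5))) {
    net <- make_lattice(lengths)
    expect_true(all(node_degrees(net) <= 2 * length(lengths)))
    g <- as_igraph(net)
    expect_equal(igraph::components(g)$no, 1L)
    expect_equal(sort(unique(round(netrent:::edge_lengths(net), 10))), 1)
  }
})

test_that("hierarchical generator matches its size law and rejects bad probabilities", {
  net <- make_hierarchical_modular(3, 8, c(0.05, 0.3, 0.9), seed = 1)
  expect_equal(n_nodes(net), 8 * 2^2)
  expect_error(make_hierarchical_modular(3, 8, c(0.9, 0.3, 0.05), seed = 1),
               "increase strictly")
  expect_error(make_hierarchical_modular(3, 8, c(0.1, 0.1, 0.9), seed = 1),
               "increase strictly")
})

test_that("degenerate probability vectors give the advertised graphs", {
  # (0, ..., 1) yields disjoint cliques of the base module size
  net <- make_hierarchical_modular(3, 6, c(0, 1e-9, 1), seed = 2)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  expect_equal(comp$no, 4L)
  expect_true(all(comp$csize == 6))
  expect_equal(n_edges(net), 4 * choose(6, 2))
  # a single level is one homogeneous block
  er <- make_hierarchical_modular(1, 32, 0.2, seed = 3)
  expect_equal(n_nodes(er), 32)
})

test_that("realised edge counts match the closed-form expectation", {
  probs <- c(0.05, 0.3, 0.9)
  expected <- expected_edges_hierarchical(3, 8, probs)
  # sum over pair classes: 112 deepest pairs, 128 mid, 256 coarse
  expect_equal(expected, 112 * 0.9 + 128 * 0.3 + 256 * 0.05)
  ms <- vapply(1:30, function(s)
    n_edges(make_hierarchical_modular(3, 8, probs, seed = s)), 0)
  expect_lt(abs(mean(ms) - expected), 4 * 7.1 / sqrt(30))
})

test_that("within-block density exceeds between-block density at every level", {
  ok <- 0
  for (s in 1:10) {
    net <- make_hierarchical_modular(3, 32, c(0.02, 0.25, 0.6), seed = s)
    blk <- attr(net, "block")
    coarse <- blk %/% 2
    dens <- function(sel) {
      pairs <- sum(outer(sel, sel, `&`)[upper.tri(diag(length(sel)))])
      inside <- sel[net$edges[, 1]] & sel[net$edges[, 2]]
      sum(inside) / pairs
    }
    within_fine <- mean(vapply(unique(blk), function(b) dens(blk == b), 0))
    within_coarse <- mean(vapply(unique(coarse), function(b) dens(coarse == b), 0))
    between <- connection_density(net)
    if (within_fine > within_coarse && within_coarse > between) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("module blocks are spatially localised in the unit cell", {
  net <- make_hierarchical_modular(3, 16, c(0.01, 0.2, 0.6), D_E = 2, seed = 5)
  blk <- attr(net, "block")
  centroids <- apply(net$coords, 2, function(v) tapply(v, blk, mean))
  # block centroids occupy distinct cells, so their spread beats the
  # within-block spread
  within <- mean(vapply(unique(blk), function(b)
    mean(sqrt(rowSums((net$coords[blk == b, , drop = FALSE] -
      matrix(centroids[as.character(b), ], sum(blk == b), 2, byrow = TRUE))^2))), 0))
  expect_gt(max(stats::dist(centroids)), within)
  expect_true(all(net$coords >= 0 & net$coords <= 1))
})

test_that("uniform rewiring conserves size and is seed-reproducible", {
  net <- make_hierarchical_modular(2, 16, c(0.1, 0.5), seed = 4)
  r1 <- rewire_random(net, seed = 11)
  r2 <- rewire_random(net, seed = 11)
  expect_identical(r1$edges, r2$edges)
  expect_equal(n_edges(r1), n_edges(net))
  expect_identical(r1$coords, net$coords)
  expect_false(identical(r1$edges, rewire_random(net, seed = 12)$edges))
  # the complete graph is the only simple graph with all pairs connected
  K <- spatial_network(clique_edges(1:6), random_coords(6))
  expect_identical(rewire_random(K, seed = 1)$edges, K$edges)
})

test_that("degree-preserving rewiring conserves the degree multiset", {
  net <- make_hierarchical_modular(2, 16, c(0.1, 0.5), seed = 6)
  rw <- rewire_degree_preserving(net, seed = 13)
  expect_equal(sort(node_degrees(rw)), sort(node_degrees(net)))
  expect_identical(rw$coords, net$coords)
  expect_false(identical(rw$edges, net$edges))
})

test_that("graphs with no valid swap are returned unchanged with a warning", {
  tri <- spatial_network(rbind(c(1, 2), c(2, 3), c(1, 3)), random_coords(3))
  expect_warning(rw <- rewire_degree_preserving(tri, seed = 1), "unchanged")
  expect_identical(rw$edges, tri$edges)
  star <- spatial_network(cbind(1, 2:4), random_coords(4))
  expect_warning(rs <- rewire_degree_preserving(star, seed = 1), "unchanged")
  expect_identical(rs$edges, star$edges)
})

test_that("noise-free power-law scatter evaluates Rent's rule exactly", {
  sc <- make_powerlaw_scatter(k = 2, p = 0.5, n_points = 50, noise_sd = 0,
                              seed = 9)
  expect_equal(sc$e, 2 * sc$n^0.5)
  fit <- rent_fit(sc$n, sc$e)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-8)
  expect_equal(fit$coefficient_k, 2, tolerance = 1e-8)
})
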