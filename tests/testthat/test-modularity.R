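test_that("Louvain recovers hand-computed modularity values", {
  # two 4-cliques joined by a bridge: Q = 2 * (6/13 - 1/4)
  bridged <- two_cliques_bridge()
  lp <- louvain_partition(bridged, seed = 1)
  expect_equal(lp$Q, 2 * (6 / 13 - 0.25), tolerance = 1e-10)
  expect_equal(length(unique(lp$membership)), 2L)

  # a single clique is one module with Q = 0
  clique <- spatial_network(clique_edges(1:5), random_coords(5))
  lc <- louvain_partition(clique, seed = 2)
  expect_equal(lc$Q, 0)
  expect_equal(length(unique(lc$membership)), 1L)

  # two disjoint cliques: e_c/m = 1/2 and (d_c/2m)^2 = 1/4 each
  ld <- louvain_partition(two_disjoint_cliques(), seed = 3)
  expect_equal(ld$Q, 0.5, tolerance = 1e-10)
  expect_error(louvain_partition(spatial_network(NULL, random_coords(3))),
               "empty")
})

test_that("strong modular structure is significant against both nulls", {
  net <- make_hierarchical_modular(2, 32, c(0.02, 0.4), seed = 4)
  sig <- modularity_significance(net, n_null = 50, seed = 5)
  expect_lt(sig$p_rand, 0.05)
  expect_lt(sig$p_func, 0.05)
  expect_gt(sig$Q, mean(sig$null_Q_rand))
})

test_that("degenerate null distributions fall back to exceedance counts", {
  # a star admits no valid degree-preserving swap, so every functional
  # surrogate is the observed graph and the null distribution degenerates
  star <- spatial_network(cbind(1, 2:6), random_coords(6))
  sig <- suppressWarnings(modularity_significance(star, n_null = 20, seed = 6))
  expect_true(sig$degenerate[["func"]])
  expect_gte(sig$p_func, 0.5)
})

test_that("observed modularity at or below the null mean is not significant", {
  # a complete graph has Q = 0 and its G(n, m) surrogates are complete too
  K <- spatial_network(clique_edges(1:12), random_coords(12))
  sig <- suppressWarnings(modularity_significance(K, n_null = 20, seed = 7))
  expect_gte(sig$p_rand, 0.5)
})

test_that("hierarchical decomposition resolves nested modules and stops at random", {
  h <- make_hierarchical_modular(3, 64, c(0.05, 0.30, 0.55), seed = 8)
  tr <- hierarchical_decompose(h, n_null = 50, seed = 9)
  expect_gte(module_tree_depth(tr), 3)
  expect_s3_class(tr, "module_tree")
  expect_equal(sort(unlist(lapply(tr$children, `[[`, "members"))),
               sort(tr$members))

  r <- rewire_random(h, seed = 10)
  trr <- hierarchical_decompose(r, n_null = 50, seed = 11)
  expect_equal(module_tree_depth(trr), 1L)
})

test_that("disjoint cliques decompose to depth 2 with cliques as leaves", {
  net <- two_disjoint_cliques(8)
  tr <- suppressWarnings(hierarchical_decompose(net, n_null = 30, seed = 12))
  expect_equal(module_tree_depth(tr), 2L)
  sizes <- sort(vapply(tr$children, function(ch) length(ch$members), 0))
  expect_equal(sizes, c(8, 8))
  expect_false(any(vapply(tr$children, `[[`, TRUE, "significant")))
})

test_that("co-classification of disjoint cliques is an exact block matrix", {
  net <- two_disjoint_cliques(4)
  C <- coclassification(net, runs = 10, seed = 13)
  expect_true(all(diag(C) == 1))
  expect_equal(unclass(C), t(unclass(C)))
  blocks <- outer(rep(1:2, each = 4), rep(1:2, each = 4), `==`)
  expect_equal(matrix(unclass(C), 8, 8), blocks * 1)
})

test_that("co-classification frequencies nest with the generating hierarchy", {
  net <- make_hierarchical_modular(3, 16, c(0.02, 0.3, 0.8), seed = 14)
  C <- unclass(coclassification(net, runs = 20, seed = 15))
  blk <- attr(net, "block")
  coarse <- blk %/% 2
  same_fine <- outer(blk, blk, `==`)
  same_coarse <- outer(coarse, coarse, `==`)
  off <- upper.tri(C)
  m_fine <- mean(C[off & same_fine])
  m_mid <- mean(C[off & !same_fine & same_coarse])
  m_out <- mean(C[off & !same_coarse])
  expect_gt(m_fine, m_mid)
  expect_gt(m_mid, m_out)
})

test_that("returned modularity values stay within their theoretical range", {
  for (s in 1:5) {
    net <- make_hierarchical_modular(2, 12, c(0.1, 0.6), seed = 20 + s)
    lp <- louvain_partition(net, runs = 3, seed = 30 + s)
    expect_gte(lp$Q, -0.5)
    expect_lte(lp$Q, 1)
  }
})
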