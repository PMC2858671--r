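test_that("box node and boundary-edge counts are exact on crafted boxes", {
  net <- make_lattice(c(4, 4))
  # a box containing every node has no boundary crossings
  all_in <- netrent:::box_counts(net, matrix(c(-0.5, -0.5), 1), matrix(5, 1, 2))
  expect_equal(all_in$n, 16L)
  expect_equal(all_in$e, 0L)
  # a box holding exactly one node crosses each of its incident edges
  corner_node <- netrent:::box_counts(net, matrix(c(-0.5, -0.5), 1),
                                      matrix(1, 1, 2))
  expect_equal(corner_node$n, 1L)
  expect_equal(corner_node$e, 2L) # grid corner has degree 2
  # half-open faces: a node on the upper face is outside
  edge_box <- netrent:::box_counts(net, matrix(c(0, 0), 1), matrix(1, 1, 2))
  expect_equal(edge_box$n, 1L)
})

test_that("box sampling is reproducible and respects its invariants", {
  net <- make_lattice(c(10, 10))
  s1 <- sample_boxes(net, 400, seed = 5)
  s2 <- sample_boxes(net, 400, seed = 5)
  expect_identical(s1$n, s2$n)
  expect_identical(s1$e, s2$e)
  expect_equal(nrow(s1), 400)
  expect_true(all(s1$n >= 1 & s1$n <= 100))
  expect_true(all(s1$e <= n_edges(net)))
  expect_error(sample_boxes(spatial_network(rbind(c(1, 2)),
                                            matrix(0, 3, 2))),
               "coincident")
})

test_that("an exact power-law box scatter is recovered exactly", {
  n <- round(exp(seq(log(2), log(400), length.out = 120)))
  fake <- data.frame(n = n, e = n^0.9)
  fit <- fit_physical_rent(fake, N = 1000)
  expect_equal(fit$exponent, 0.9, tolerance = 1e-6)
  expect_error(fit_physical_rent(fake[1:10, ], N = 1000), "50")
})

test_that("boxes beyond half the network are excluded from the fit", {
  n <- c(round(exp(seq(log(2), log(400), length.out = 80))),
         rep(600, 40))
  fake <- data.frame(n = n, e = c(n[1:80]^0.9, rep(1, 40)))
  fit <- fit_physical_rent(fake, N = 1000)
  expect_false(any(fit$region_mask[81:120]))
  expect_equal(fit$exponent, 0.9, tolerance = 1e-6)
})

test_that("lattice box placement recovers the 2-D exponent", {
  net <- make_lattice(c(16, 16))
  fit <- fit_physical_rent(sample_boxes(net, 2000, seed = 6), 256)
  expect_gt(fit$exponent, 0.4)
  expect_lt(fit$exponent, 0.6)
})

test_that("the fitted exponent is invariant to uniform coordinate rescaling", {
  net <- make_lattice(c(12, 12))
  f1 <- fit_physical_rent(sample_boxes(net, 1500, seed = 7), 144)
  scaled <- net
  scaled$coords <- scaled$coords * 7.3
  f2 <- fit_physical_rent(sample_boxes(scaled, 1500, seed = 7), 144)
  expect_equal(f1$exponent, f2$exponent, tolerance = 1e-10)
})

test_that("random placement does not lower the physical exponent of a lattice", {
  net <- make_lattice(c(12, 12))
  ok <- 0
  for (s in 1:4) {
    fo <- fit_physical_rent(sample_boxes(net, 1500, seed = 30 + s), 144)
    fr <- fit_physical_rent(sample_boxes(rewire_random(net, seed = s),
                                         1500, seed = 30 + s), 144)
    if (fr$exponent >= fo$exponent) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("fitted exponents respect the theoretical embedding bound", {
  net <- make_hierarchical_modular(4, 8, c(0.02, 0.05, 0.12, 0.3),
                                   D_E = 3, seed = 9)
  topo <- fit_topological_rent(recursive_partition(net, seed = 10))
  fit <- fit_physical_rent(sample_boxes(net, 3000, seed = 11), n_nodes(net))
  p_min <- min_physical_exponent(min(topo$exponent, 0.99), 3)
  # noise allowance: both estimates carry sampling error
  halfwidth <- (fit$ci95[2] - fit$ci95[1]) / 2 +
    (topo$ci95[2] - topo$ci95[1]) / 2
  expect_gte(fit$exponent, p_min - 2 * halfwidth)

  grid <- make_lattice(c(12, 12))
  gfit <- fit_physical_rent(sample_boxes(grid, 2000, seed = 12), 144)
  gtopo <- fit_topological_rent(recursive_partition(grid, seed = 13))
  g_min <- min_physical_exponent(min(gtopo$exponent, 0.99), 2)
  ghw <- (gfit$ci95[2] - gfit$ci95[1]) / 2 + (gtopo$ci95[2] - gtopo$ci95[1]) / 2
  expect_gte(gfit$exponent, g_min - 2 * ghw)
})

test_that("the minimum physical exponent is the max of bound and p_T", {
  expect_equal(min_physical_exponent(0.4, 3), 2 / 3)
  expect_equal(min_physical_exponent(0.3, 2), 0.5)
  expect_equal(min_physical_exponent(0.77, 3), 0.77)
  expect_error(min_physical_exponent(1.2, 3), "p_T")
  expect_error(min_physical_exponent(0.5, 4), "D_E")
})
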