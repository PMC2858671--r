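# shared fixtures and brute-force oracles (small n only)

clique_edges <- function(ids) t(utils::combn(ids, 2))

random_coords <- function(n, d = 2, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(n * d), n, d)
}

two_cliques_bridge <- function(k = 4) {
  edges <- rbind(clique_edges(1:k), clique_edges((k + 1):(2 * k)),
                 c(k, k + 1))
  spatial_network(edges, random_coords(2 * k))
}

two_disjoint_cliques <- function(k = 4) {
  edges <- rbind(clique_edges(1:k), clique_edges((k + 1):(2 * k)))
  spatial_network(edges, random_coords(2 * k))
}

# exhaustive minimum balanced cut: all splits with ||A|-|B|| <= max(1, tol*n)
brute_min_cut <- function(net, balance_tolerance = 0.1) {
  n <- n_nodes(net)
  edges <- net$edges
  maxdiff <- max(1, balance_tolerance * n)
  best <- Inf
  for (sz in seq_len(n - 1)) {
    if (abs(2 * sz - n) > maxdiff) next
    combs <- utils::combn(n, sz)
    for (k in seq_len(ncol(combs))) {
      inside <- logical(n)
      inside[combs[, k]] <- TRUE
      cut <- sum(xor(inside[edges[, 1]], inside[edges[, 2]]))
      best <- min(best, cut)
    }
  }
  best
}

# exhaustive minimum-total-length connected subgraph with m edges
brute_min_wiring <- function(coords, m) {
  n <- nrow(coords)
  pairs <- t(utils::combn(n, 2))
  d <- sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                       coords[pairs[, 2], , drop = FALSE])^2))
  best <- Inf
  subs <- utils::combn(nrow(pairs), m)
  for (k in seq_len(ncol(subs))) {
    sel <- subs[, k]
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
    if (igraph::components(g)$no == 1) best <- min(best, sum(d[sel]))
  }
  best
}
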