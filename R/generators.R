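#' Regular lattice with unit spacing
#'
#' Grid nodes at integer coordinates with nearest-neighbour (unit-distance)
#' edges only. A lattice has topological dimension equal to its grid
#' dimension, which makes it the ground-truth fixture for the Rent-exponent
#' estimators (a D-dimensional lattice has Rent exponent 1 - 1/D).
#'
#' @param lengths integer vector of 1 to 3 side lengths, each >= 2. A
#'   1-dimensional chain is embedded in the plane (y = 0) since the package
#'   requires an embedding dimension of 2 or 3.
#' @return a [spatial_network()].
#' @examples
#' make_lattice(c(4, 4)) # 16 nodes, 24 edges
#' @export
make_lattice <- function(lengths) {
  lengths <- as.integer(lengths)
  if (length(lengths) < 1 || length(lengths) > 3) {
    stop("lengths must have 1 to 3 entries")
  }
  if (any(lengths < 2)) stop("each side length must be >= 2")
  dims <- length(lengths)
  grid <- as.matrix(expand.grid(lapply(lengths, function(L) 0:(L - 1))))
  colnames(grid) <- c("x", "y", "z")[seq_len(dims)]
  N <- nrow(grid)
  idx <- array(seq_len(N), dim = lengths)
  edges <- NULL
  for (d in seq_len(dims)) {
    sel_from <- lapply(lengths, seq_len)
    sel_from[[d]] <- seq_len(lengths[d] - 1)
    sel_to <- sel_from
    sel_to[[d]] <- sel_from[[d]] + 1
    from <- do.call(`[`, c(list(idx), sel_from))
    to <- do.call(`[`, c(list(idx), sel_to))
    edges <- rbind(edges, cbind(as.vector(from), as.vector(to)))
  }
  if (dims == 1) grid <- cbind(grid, y = 0)
  spatial_network(edges, grid)
}

#' Spatially embedded fractal hierarchical-modular network
#'
#' Nested stochastic block structure: `base_module_size * 2^(levels-1)` nodes
#' are organised in a balanced binary hierarchy of blocks. The probability of
#' an edge between two nodes is the probability assigned to the deepest level
#' at which they share a block, so probabilities must increase strictly from
#' the coarsest level (level 1, the whole network) to the deepest: submodules
#' are denser than the modules containing them.
#'
#' Coordinates are spatially nested: each binary split of the hierarchy also
#' bisects the current coordinate cell of the unit square/cube (cycling the
#' axes), and nodes are placed uniformly inside their deepest block's cell.
#' Modules are therefore spatially localised, emulating the anatomical
#' localisation of modules in real connectomes; dense submodules have short
#' internal wiring, which is what makes the wiring-cost/complexity trade-off
#' observable on these fixtures.
#'
#' @param levels number of hierarchical levels (>= 1).
#' @param base_module_size nodes per deepest block.
#' @param level_probabilities vector of `levels` connection probabilities,
#'   coarsest first, strictly increasing.
#' @param D_E embedding dimension (2 or 3, default 3).
#' @param seed optional integer seed, recorded in the result.
#' @return a [spatial_network()] with attributes `seed` and `block` (the
#'   deepest-level block label of every node).
#' @export
make_hierarchical_modular <- function(levels, base_module_size,
                                      level_probabilities,
                                      D_E = 3, seed = NULL) {
  levels <- as.integer(levels)
  base_module_size <- as.integer(base_module_size)
  if (levels < 1) stop("levels must be >= 1")
  if (base_module_size < 1) stop("base_module_size must be >= 1")
  p <- as.numeric(level_probabilities)
  if (length(p) != levels) stop("need one probability per level")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (levels > 1 && any(diff(p) <= 0)) {
    stop("level probabilities must increase strictly from coarsest to deepest")
  }
  if (!is.null(seed)) set.seed(seed)

  N <- base_module_size * 2L^(levels - 1L)
  # block id of each node at each level; level 1 is the whole network
  node <- seq_len(N) - 1L
  block <- sapply(seq_len(levels), function(l) {
    node %/% (base_module_size * 2L^(levels - l))
  })
  block <- matrix(block, nrow = N)

  pairs <- which(upper.tri(matrix(0, N, N)), arr.ind = TRUE)
  # deepest level at which the two endpoints share a block
  lev <- rep(1L, nrow(pairs))
  for (l in seq_len(levels)) {
    same <- block[pairs[, 1], l] == block[pairs[, 2], l]
    lev[same] <- l
  }
  keep <- stats::runif(nrow(pairs)) < p[lev]
  edges <- pairs[keep, , drop = FALSE]

  # spatially nested coordinates: binary splits of the unit cell per level
  lo <- matrix(0, N, D_E)
  hi <- matrix(1, N, D_E)
  if (levels > 1) {
    for (l in 2:levels) {
      axis <- (l - 2L) %% D_E + 1L
      bit <- block[, l] %% 2L
      mid <- (lo[, axis] + hi[, axis]) / 2
      hi[bit == 0L, axis] <- mid[bit == 0L]
      lo[bit == 1L, axis] <- mid[bit == 1L]
    }
  }
  coords <- lo + matrix(stats::runif(N * D_E), N, D_E) * (hi - lo)
  colnames(coords) <- c("x", "y", "z")[seq_len(D_E)]

  net <- spatial_network(edges, coords)
  attr(net, "seed") <- seed
  attr(net, "block") <- block[, levels]
  net
}

#' Expected edge count of the hierarchical generator
#'
#' Closed-form sum over pair classes: the number of node pairs whose deepest
#' shared level is `l`, times the level-`l` probability.
#'
#' @inheritParams make_hierarchical_modular
#' @return expected number of edges.
#' @export
expected_edges_hierarchical <- function(levels, base_module_size,
                                        level_probabilities) {
  p <- as.numeric(level_probabilities)
  b <- base_module_size
  total <- 0
  for (l in seq_len(levels)) {
    n_blocks <- 2^(l - 1)
    block_size <- b * 2^(levels - l)
    pairs_within <- n_blocks * choose(block_size, 2)
    pairs_deeper <- if (l < levels) {
      2 * n_blocks * choose(block_size / 2, 2)
    } else 0
    total <- total + (pairs_within - pairs_deeper) * p[l]
  }
  total
}

#' Uniformly random rewiring at fixed size
#'
#' Resamples the edge set uniformly among simple graphs with the same number
#' of nodes and edges; node identities and coordinates are untouched. This is
#' the "pure random" baseline used for null comparisons.
#'
#' @param net a [spatial_network()].
#' @param seed optional integer seed.
#' @return a [spatial_network()] with the same nodes and coordinates.
#' @export
rewire_random <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- n_nodes(net)
  m <- n_edges(net)
  n_pairs <- N * (N - 1) / 2
  if (m > n_pairs) stop("more edges than node pairs")
  sel <- sample.int(n_pairs, m)
  # decode linear upper-triangle index (column-major) to (i, j), i < j
  j <- ceiling((1 + sqrt(1 + 8 * sel)) / 2)
  i <- sel - (j - 1) * (j - 2) / 2
  replace_edges(net, cbind(as.integer(i), as.integer(j)))
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Double-edge swaps that preserve every node's degree. Swaps that would
#' create a self-loop or duplicate edge are rejected and retried; only
#' accepted swaps count toward the budget of `ceiling(swaps_per_edge * m)`
#' rewirings, so each edge is rewired `swaps_per_edge` times on average.
#' This is the "functional random" null model.
#'
#' @param net a [spatial_network()] with at least 2 edges.
#' @param swaps_per_edge mean number of accepted rewirings per edge
#'   (default 15).
#' @param seed optional integer seed.
#' @return a [spatial_network()] with identical degree sequence. Graphs with
#'   no valid swap (e.g. stars, triangles) are returned unchanged with a
#'   warning.
#' @export
rewire_degree_preserving <- function(net, swaps_per_edge = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- n_edges(net)
  if (m < 2) stop("need at least 2 edges to swap")
  target <- ceiling(swaps_per_edge * m)
  res <- maslov_rewire_core(net$edges - 1L, n_nodes(net),
                            target, max(1000, 200 * target))
  if (res$accepted == 0) {
    warning("no valid degree-preserving swap exists; network unchanged")
    return(net)
  }
  if (res$accepted < target) {
    warning(sprintf("only %d of %d swaps accepted before the attempt budget",
                    as.integer(res$accepted), as.integer(target)))
  }
  replace_edges(net, res$edges + 1L)
}

#' Power-law (n, e) scatter with multiplicative noise
#'
#' Draws points on `e = k * n^p * exp(eps)`, `eps ~ Normal(0, noise_sd^2)`,
#' with `n` log-uniform over `n_range`. Used for parameter-recovery tests of
#' the Rent-exponent estimators.
#'
#' @param k power-law coefficient (> 0).
#' @param p exponent in (0, 1].
#' @param n_points number of points.
#' @param noise_sd standard deviation of the log-scale noise (>= 0).
#' @param n_range range of `n`, sampled log-uniformly.
#' @param seed optional integer seed.
#' @return data frame with columns `n` and `e`.
#' @export
make_powerlaw_scatter <- function(k, p, n_points = 200, noise_sd = 0.1,
                                  n_range = c(10, 1e4), seed = NULL) {
  if (k <= 0) stop("k must be positive")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- exp(stats::runif(n_points, log(n_range[1]), log(n_range[2])))
  e <- k * n^p * exp(stats::rnorm(n_points, 0, noise_sd))
  data.frame(n = n, e = e)
}
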