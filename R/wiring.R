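#' Node-to-node spacing
#'
#' The characteristic spacing `delta` between neighbouring nodes of the
#' embedding: the mean over nodes of the Euclidean distance to the nearest
#' other node. It is homogeneous of degree 1 in the coordinates (doubling
#' all coordinates doubles `delta`) and equals the common value when all
#' pairwise distances are equal.
#'
#' @param net a [spatial_network()] with N >= 2, not all nodes coincident.
#' @return the spacing, in the coordinate length units.
#' @export
node_spacing <- function(net) {
  if (n_nodes(net) < 2) stop("need at least 2 nodes")
  nnd <- nn_distances(net$coords)
  delta <- mean(nnd)
  if (delta == 0) stop("all nodes coincident: degenerate geometry")
  delta
}

#' Mean connection distance in spacing units
#'
#' The mean Euclidean length of the network's edges divided by the
#' node-to-node spacing [node_spacing()]; dimensionless and invariant under
#' uniform rescaling of the coordinates.
#'
#' @param net a [spatial_network()] with at least one edge.
#' @return the normalised mean connection distance `L_bar`.
#' @export
mean_connection_distance <- function(net) {
  if (n_edges(net) < 1) stop("network has no edges")
  mean(edge_lengths(net)) / node_spacing(net)
}

#' Cost-efficiency coefficient kappa
#'
#' For a network of `N` nodes whose topological dimension `D_T` exceeds its
#' embedding dimension `D_E`, the expected mean connection distance (in
#' spacing units) of a cost-efficiently embedded network is
#' `L_bar = kappa * N^(1/D_E - 1/D_T)` with `kappa` of order unity.
#' Inverting gives `kappa = L_bar / N^(1/D_E - 1/D_T)`: values near 1
#' indicate a cost-efficient embedding, large values wiring that is
#' physically extended beyond the efficient optimum.
#'
#' @param L_bar normalised mean connection distance
#'   ([mean_connection_distance()]).
#' @param N number of nodes (>= 2).
#' @param D_T topological dimension (must exceed `D_E`).
#' @param D_E embedding dimension.
#' @return the coefficient kappa.
#' @export
cost_efficiency_kappa <- function(L_bar, N, D_T, D_E) {
  if (N < 2) stop("N must be >= 2")
  if (D_T <= D_E) {
    stop("kappa is defined for D_T > D_E; lattice-like networks ",
         "(D_T <= D_E) are in the regime where wiring can be minimal")
  }
  L_bar / N^(1 / D_E - 1 / D_T)
}

#' Minimally rewired baseline
#'
#' Keeps every node in place and replaces the edge set by the Euclidean
#' minimum spanning tree plus the shortest remaining candidate edges, added
#' in ascending distance order until the edge count matches the input -- the
#' cheapest connected wiring of the same density over the same node
#' positions. Distance ties are broken lexicographically by node pair, so
#' the result is deterministic. For very large networks (N > `knn_cutoff`)
#' the non-tree candidate edges are restricted to the `k = 50` nearest
#' neighbours of each node.
#'
#' @param net a [spatial_network()] with N >= 2.
#' @param knn_cutoff switch to the k-nearest-neighbour candidate set above
#'   this many nodes (default 5000).
#' @return a [spatial_network()] with the same nodes and coordinates and
#'   the same number of edges (at least N - 1: connectivity is enforced).
#' @export
rewire_minimal <- function(net, knn_cutoff = 5000) {
  N <- n_nodes(net)
  if (N < 2) stop("need at least 2 nodes")
  m_target <- n_edges(net)
  dm <- node_distances(net)
  if (N > knn_cutoff) {
    cand <- NULL
    k <- min(50, N - 1)
    for (i in seq_len(N)) {
      nb <- order(dm[i, ])[2:(k + 1)]
      cand <- rbind(cand, cbind(pmin(i, nb), pmax(i, nb)))
    }
    cand <- unique(cand)
  } else {
    cand <- which(upper.tri(dm), arr.ind = TRUE)
  }
  w <- dm[cand]
  ord <- order(w, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]

  parent <- seq_len(N)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(nrow(cand))
  n_tree <- 0L
  for (kk in seq_len(nrow(cand))) {
    ra <- find(cand[kk, 1]); rb <- find(cand[kk, 2])
    if (ra != rb) {
      parent[ra] <- rb
      in_tree[kk] <- TRUE
      n_tree <- n_tree + 1L
      if (n_tree == N - 1L) break
    }
  }
  if (n_tree < N - 1L) stop("candidate edge set does not span the nodes")
  keep <- in_tree
  m <- n_tree
  if (m_target < m) {
    warning("input has fewer edges than a spanning tree; returning the tree")
  }
  for (kk in which(!in_tree)) {
    if (m >= m_target) break
    keep[kk] <- TRUE
    m <- m + 1L
  }
  replace_edges(net, cand[keep, , drop = FALSE])
}

#' Wiring-cost report
#'
#' Bundles the spacing `delta`, the normalised mean connection distance
#' `L_bar`, the raw mean edge length (in coordinate units, so comparisons
#' between rewired variants do not depend on the spacing normalisation) and
#' -- when a topological dimension exceeding `D_E` is supplied -- the
#' cost-efficiency coefficient `kappa`.
#'
#' @param net a [spatial_network()] with at least one edge.
#' @param D_T optional topological dimension estimate for `kappa`.
#' @return object of class `wiring_report` with fields `delta`, `L_bar`,
#'   `mean_edge_length`, `kappa` (NA when `D_T` is missing or `<= D_E`).
#' @export
wiring_report <- function(net, D_T = NULL) {
  delta <- node_spacing(net)
  raw <- mean(edge_lengths(net))
  L_bar <- raw / delta
  kappa <- NA_real_
  if (!is.null(D_T) && is.finite(D_T) && D_T > net$D_E) {
    kappa <- cost_efficiency_kappa(L_bar, n_nodes(net), D_T, net$D_E)
  }
  structure(list(delta = delta, L_bar = L_bar, mean_edge_length = raw,
                 kappa = kappa, N = n_nodes(net), D_E = net$D_E),
            class = "wiring_report")
}

#' @export
print.wiring_report <- function(x, ...) {
  cat(sprintf("Wiring: delta = %.4g, L_bar = %.4g, mean edge length = %.4g\n",
              x$delta, x$L_bar, x$mean_edge_length))
  cat(if (is.na(x$kappa)) "  kappa: not applicable (D_T <= D_E or unknown)\n"
      else sprintf("  kappa = %.4g\n", x$kappa))
  invisible(x)
}
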