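#' Random Euclidean box sampling
#'
#' Places `n_boxes` axis-aligned square/cubic boxes fully inside the
#' coordinate bounding volume: the side length is uniform between the 5th
#' percentile of nearest-neighbour distances and the full extent (clipped
#' per axis to the bounding volume), and the corner uniform over positions
#' keeping the box inside. For each box it records `n`, the number of nodes
#' strictly inside (half-open boxes: a node on a face counts as inside iff
#' its coordinate is below the upper face), and `e`, the number of edges
#' with exactly one endpoint inside. Boxes containing no node are discarded
#' and resampled.
#'
#' @param net a [spatial_network()] with at least 3 nodes spanning a
#'   nondegenerate bounding volume.
#' @param n_boxes number of boxes (default 5000).
#' @param seed optional integer seed.
#' @return object of class `box_sample`: a data frame with columns `n` and
#'   `e`, with the box geometry in attributes `corner` and `side`.
#' @export
sample_boxes <- function(net, n_boxes = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- n_nodes(net)
  if (N < 3) stop("need at least 3 nodes")
  X <- net$coords
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  extent <- hi - lo
  if (all(extent == 0)) stop("all nodes coincident: degenerate geometry")
  d <- stats::dist(X)
  if (max(d) == 0) stop("all nodes coincident: degenerate geometry")
  nnd <- nn_distances(X)
  smin <- stats::quantile(nnd[nnd > 0], 0.05, names = FALSE)
  smax <- max(extent)

  want <- n_boxes
  out_n <- integer(0); out_e <- integer(0)
  out_corner <- NULL; out_side <- NULL
  rounds <- 0
  while (want > 0 && rounds < 200) {
    rounds <- rounds + 1
    B <- want
    s <- stats::runif(B, smin, smax)
    side <- outer(s, extent, pmin) # per-axis clip to the bounding volume
    corner <- matrix(stats::runif(B * ncol(X)), B) * (
      matrix(extent, B, ncol(X), byrow = TRUE) - side) +
      matrix(lo, B, ncol(X), byrow = TRUE)
    cnt <- box_counts(net, corner, side)
    keep <- cnt$n > 0
    out_n <- c(out_n, cnt$n[keep])
    out_e <- c(out_e, cnt$e[keep])
    out_corner <- rbind(out_corner, corner[keep, , drop = FALSE])
    out_side <- rbind(out_side, side[keep, , drop = FALSE])
    want <- n_boxes - length(out_n)
  }
  if (want > 0) stop("could not place boxes containing nodes")
  structure(data.frame(n = out_n, e = out_e),
            corner = out_corner, side = out_side,
            class = c("box_sample", "data.frame"))
}

# nodes-inside / boundary-edge counts for given boxes; half-open intervals
# [corner, corner + side)
box_counts <- function(net, corner, side) {
  X <- net$coords
  B <- nrow(corner)
  edges <- net$edges
  nvec <- integer(B); evec <- integer(B)
  chunk <- max(1L, floor(2e7 / max(1L, nrow(edges))))
  for (start in seq(1L, B, by = chunk)) {
    ix <- start:min(B, start + chunk - 1L)
    inside <- matrix(TRUE, length(ix), nrow(X))
    for (dcol in seq_len(ncol(X))) {
      xo <- matrix(X[, dcol], length(ix), nrow(X), byrow = TRUE)
      inside <- inside & xo >= corner[ix, dcol] &
        xo < corner[ix, dcol] + side[ix, dcol]
    }
    nvec[ix] <- rowSums(inside)
    if (nrow(edges)) {
      evec[ix] <- rowSums(inside[, edges[, 1], drop = FALSE] !=
                            inside[, edges[, 2], drop = FALSE])
    }
  }
  list(n = nvec, e = evec)
}

nn_distances <- function(X) {
  dm <- as.matrix(stats::dist(X))
  diag(dm) <- Inf
  apply(dm, 1, min)
}

#' Physical Rent exponent from a box sample
#'
#' Robust (iteratively reweighted least squares, bisquare) regression of
#' `log e` on `log n` over the boxes that contain fewer than half the
#' network's nodes -- larger boxes sit in the boundary-affected Region II
#' and are excluded -- and have `n >= 2`, `e >= 1`.
#'
#' @param sample a `box_sample` from [sample_boxes()] (or any data frame
#'   with columns `n` and `e`).
#' @param N total number of nodes in the network the sample was drawn from.
#' @return a [rent_fit()] object; the physical Rent exponent is `$exponent`.
#' @export
fit_physical_rent <- function(sample, N) {
  region <- sample$n < N / 2 & sample$n >= 2 & sample$e >= 1
  if (sum(region) < 50) {
    stop("fewer than 50 usable boxes; sample more boxes or use a larger network")
  }
  rent_fit(sample$n, sample$e, method = "irls", region = region)
}

#' Theoretical minimum physical Rent exponent
#'
#' For a network with topological Rent exponent `p_T` embedded in `D_E`
#' Euclidean dimensions, the most efficient possible placement attains
#' `p_min = max(p_T, 1 - 1/D_E)`: no embedding can beat the intrinsic
#' topological exponent, nor the `1 - 1/D_E` floor imposed by the surface
#' to volume ratio of blocks of the embedding space (2/3 in 3-D, 1/2 in
#' 2-D).
#'
#' @param p_T topological Rent exponent in `[0, 1)`.
#' @param D_E embedding dimension, 2 or 3.
#' @return the minimum physical Rent exponent.
#' @examples
#' min_physical_exponent(0.4, 3) # the Euclidean floor 2/3
#' min_physical_exponent(0.77, 3) # the topological exponent itself
#' @export
min_physical_exponent <- function(p_T, D_E) {
  if (any(p_T < 0 | p_T >= 1)) stop("p_T must lie in [0, 1)")
  if (!all(D_E %in% c(2, 3))) stop("D_E must be 2 or 3")
  pmax(p_T, 1 - 1 / D_E)
}
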