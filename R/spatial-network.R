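#' Construct a spatially embedded network
#'
#' A `spatial_network` is the universal input of the package: an undirected
#' simple graph whose nodes carry coordinates in 2- or 3-dimensional Euclidean
#' space (arbitrary length units, e.g. mm for a connectome, um for a circuit).
#'
#' @param edges two-column matrix or data frame of edges, given either as node
#'   ids (matching `rownames(coords)` / `node_ids`) or as integer indices.
#'   Symmetric duplicates `(a,b)`/`(b,a)` are collapsed to a single edge.
#' @param coords numeric matrix with one row per node and 2 or 3 columns; row
#'   names are used as node ids when `node_ids` is missing.
#' @param node_ids optional character vector of node labels.
#' @return An object of class `spatial_network` with elements `nodes`
#'   (character ids), `coords` (numeric matrix), `edges` (m x 2 integer matrix,
#'   each row `i < j`), and `D_E` (embedding dimension).
#' @examples
#' net <- spatial_network(rbind(c(1, 2), c(2, 3)),
#'                        cbind(x = c(0, 1, 2), y = c(0, 0, 0)))
#' net
#' @export
spatial_network <- function(edges, coords, node_ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(node_ids)) {
    node_ids <- rownames(coords)
    if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(coords)))
  }
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) stop("duplicate node ids")
  if (length(node_ids) != nrow(coords)) {
    stop("node_ids and coords disagree on the number of nodes")
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  D_E <- ncol(coords)
  if (!D_E %in% c(2L, 3L)) stop("embedding dimension must be 2 or 3")
  rownames(coords) <- node_ids

  if (is.null(edges) || NROW(edges) == 0) {
    eidx <- matrix(integer(0), 0, 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns")
    if (is.character(edges)) {
      i <- match(edges[, 1], node_ids)
      j <- match(edges[, 2], node_ids)
      if (anyNA(i) || anyNA(j)) {
        bad <- unique(c(edges[, 1][is.na(i)], edges[, 2][is.na(j)]))
        stop("unknown node id(s) in edge list: ", paste(bad, collapse = ", "))
      }
    } else {
      i <- as.integer(edges[, 1])
      j <- as.integer(edges[, 2])
      if (any(i < 1 | i > length(node_ids) | j < 1 | j > length(node_ids))) {
        stop("edge index out of range")
      }
    }
    if (any(i == j)) stop("self-loop encountered in edge list")
    eidx <- cbind(pmin(i, j), pmax(i, j))
    eidx <- unique(eidx)
    eidx <- eidx[order(eidx[, 1], eidx[, 2]), , drop = FALSE]
  }
  structure(list(nodes = node_ids, coords = coords,
                 edges = eidx, D_E = D_E),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("Spatial network: %d nodes, %d edges, D_E = %d\n",
              n_nodes(x), n_edges(x), x$D_E))
  cat(sprintf("  connection density: %.4g\n", connection_density(x)))
  invisible(x)
}

#' @export
summary.spatial_network <- function(object, ...) {
  deg <- node_degrees(object)
  out <- list(N = n_nodes(object), m = n_edges(object), D_E = object$D_E,
              density = connection_density(object),
              degree_range = range(deg), mean_degree = mean(deg))
  class(out) <- "summary.spatial_network"
  out
}

#' @export
print.summary.spatial_network <- function(x, ...) {
  cat(sprintf("N = %d, m = %d, D_E = %d, density = %.4g\n",
              x$N, x$m, x$D_E, x$density))
  cat(sprintf("degree: mean %.2f, range [%d, %d]\n",
              x$mean_degree, x$degree_range[1], x$degree_range[2]))
  invisible(x)
}

#' @export
plot.spatial_network <- function(x, ...) {
  xy <- x$coords[, 1:2, drop = FALSE]
  graphics::plot(xy, pch = 16, cex = 0.6, asp = 1,
                 xlab = colnames(xy)[1], ylab = colnames(xy)[2], ...)
  if (n_edges(x) > 0) {
    graphics::segments(xy[x$edges[, 1], 1], xy[x$edges[, 1], 2],
                       xy[x$edges[, 2], 1], xy[x$edges[, 2], 2],
                       col = grDevices::grey(0.4, 0.5))
  }
  invisible(x)
}

#' Basic size accessors
#'
#' @param net a `spatial_network`.
#' @return `n_nodes`/`n_edges` return integers; `connection_density` returns
#'   2m / (N (N - 1)); `node_degrees` a named integer vector.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_nodes
#' @export
connection_density <- function(net) {
  N <- n_nodes(net)
  if (N < 2) return(0)
  2 * n_edges(net) / (N * (N - 1))
}

#' @rdname n_nodes
#' @export
node_degrees <- function(net) {
  deg <- tabulate(c(net$edges[, 1], net$edges[, 2]), nbins = n_nodes(net))
  names(deg) <- net$nodes
  deg
}

#' Convert to an igraph graph
#'
#' Node order and ids are preserved in the `name` vertex attribute.
#' @param net a `spatial_network`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::add_edges(g, t(net$edges))
  igraph::V(g)$name <- net$nodes
  g
}

#' Pairwise Euclidean distances between nodes
#' @param net a `spatial_network`.
#' @return dense N x N matrix of Euclidean distances.
#' @export
node_distances <- function(net) {
  as.matrix(stats::dist(net$coords))
}

edge_lengths <- function(net) {
  d <- net$coords[net$edges[, 1], , drop = FALSE] -
    net$coords[net$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

replace_edges <- function(net, eidx) {
  eidx <- cbind(pmin(eidx[, 1], eidx[, 2]), pmax(eidx[, 1], eidx[, 2]))
  eidx <- unique(eidx)
  net$edges <- eidx[order(eidx[, 1], eidx[, 2]), , drop = FALSE]
  net
}
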