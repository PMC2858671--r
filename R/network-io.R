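#' Read a spatially embedded network from text files
#'
#' Edge and coordinate files are whitespace- or tab-delimited text; lines
#' starting with `#` are comments; node ids are opaque strings. The edge file
#' has two columns of node ids. The coordinate file has a node id followed by
#' 2 or 3 numeric columns; the embedding dimension is inferred from the column
#' count and must be consistent across rows.
#'
#' @param edge_path path to the two-column edge list.
#' @param coord_path path to the coordinate table.
#' @return a [spatial_network()].
#' @seealso [write_spatial_network()], [write_network_json()]
#' @export
read_spatial_network <- function(edge_path, coord_path) {
  cfields <- read_token_lines(coord_path)
  arity <- lengths(cfields)
  if (length(unique(arity)) > 1) {
    stop("inconsistent coordinate arity: rows have ",
         paste(sort(unique(arity)) - 1, collapse = " and "),
         " coordinate columns")
  }
  if (!arity[1] %in% c(3L, 4L)) {
    stop("coordinate file must have a node id plus 2 or 3 numeric columns")
  }
  ids <- vapply(cfields, `[`, "", 1L)
  coords <- do.call(rbind, lapply(cfields, function(f) as.numeric(f[-1])))
  if (anyNA(coords)) stop("non-numeric coordinate value")
  rownames(coords) <- ids

  efields <- read_token_lines(edge_path)
  if (length(efields) && any(lengths(efields) < 2)) {
    stop("edge file rows must have two node ids")
  }
  edges <- do.call(rbind, lapply(efields, function(f) f[1:2]))
  if (is.null(edges)) edges <- matrix(character(0), 0, 2)
  spatial_network(edges, coords, node_ids = ids)
}

read_token_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  strsplit(lines, "[ \t]+")
}

#' Write a network as edge-list and coordinate text files
#'
#' The round trip through [read_spatial_network()] is the identity on nodes,
#' coordinates and edges.
#'
#' @param net a [spatial_network()].
#' @param edge_path,coord_path output paths.
#' @param header optional comment line (e.g. recording a generator seed)
#'   written atop both files.
#' @return `net`, invisibly.
#' @export
write_spatial_network <- function(net, edge_path, coord_path, header = NULL) {
  hdr <- if (is.null(header)) character(0) else paste0("# ", header)
  elines <- c(hdr, paste(net$nodes[net$edges[, 1]], net$nodes[net$edges[, 2]]))
  writeLines(elines, edge_path)
  clines <- c(hdr, paste(net$nodes,
                         apply(net$coords, 1, paste, collapse = " ")))
  writeLines(clines, coord_path)
  invisible(net)
}

#' Write a network as a single JSON document
#'
#' @param net a [spatial_network()].
#' @param path output path.
#' @return `net`, invisibly.
#' @export
write_network_json <- function(net, path) {
  doc <- list(nodes = net$nodes,
              coords = unname(apply(net$coords, 1, as.list)),
              D_E = net$D_E,
              edges = unname(apply(net$edges, 1, function(e)
                list(net$nodes[e[1]], net$nodes[e[2]]))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(net)
}

#' Validate a symmetric weight matrix
#'
#' @param W square numeric matrix (correlation or connection-probability
#'   units); the diagonal is ignored.
#' @param labels optional node labels (defaults to the matrix dimnames).
#' @param tol symmetry tolerance.
#' @return `W` with dimnames set, invisibly checked.
#' @export
weight_matrix <- function(W, labels = NULL, tol = 1e-9) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (!all(is.finite(W))) stop("weight matrix entries must be finite")
  if (max(abs(W - t(W))) > tol) stop("weight matrix is not symmetric")
  if (is.null(labels)) labels <- rownames(W)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  W
}

#' Threshold a weight matrix into an edge set
#'
#' An edge `(i, j)` is retained iff `W[i, j] > tau` (strict inequality, so a
#' threshold equal to a weight excludes that pair). With `density` instead of
#' `tau`, the smallest threshold achieving connection density at least
#' `density` is used; ties at the cut value are all included and the achieved
#' density is reported as an attribute.
#'
#' @param W symmetric weight matrix (see [weight_matrix()]).
#' @param tau absolute threshold, or
#' @param density target connection density in (0, 1].
#' @return two-column character matrix of node-id pairs, with attributes
#'   `tau` and `density` (achieved).
#' @export
threshold_matrix <- function(W, tau = NULL, density = NULL) {
  W <- weight_matrix(W)
  labels <- rownames(W)
  N <- nrow(W)
  iu <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  n_pairs <- length(w)

  if (is.null(tau) == is.null(density)) {
    stop("supply exactly one of tau or density")
  }
  if (is.null(tau)) {
    if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
    sw <- sort(w, decreasing = TRUE)
    k <- ceiling(density * n_pairs)
    cut <- sw[k]
    if (all(w == w[1])) {
      warning("all off-diagonal weights equal: density rule is all-or-nothing")
    }
    keep <- w >= cut # includes all ties at the cut value
    tau_used <- cut
  } else {
    keep <- w > tau
    tau_used <- tau
  }
  edges <- cbind(labels[iu[keep, 1]], labels[iu[keep, 2]])
  structure(edges, tau = tau_used,
            density = sum(keep) / n_pairs)
}

#' Connectivity-backbone extraction from a weight matrix
#'
#' Retains the maximum-weight spanning tree of the positive-weight graph, then
#' adds the remaining edges in order of decreasing weight until the mean
#' degree `2 m / N` reaches `target_mean_degree`. Ties are broken
#' lexicographically by node pair, so the result is deterministic.
#'
#' @param W nonnegative symmetric weight matrix; the graph implied by the
#'   positive weights must be connected.
#' @param target_mean_degree target average degree (default 4).
#' @return two-column character matrix of node-id pairs.
#' @export
backbone_extraction <- function(W, target_mean_degree = 4) {
  W <- weight_matrix(W)
  if (any(W < 0)) stop("weights must be nonnegative")
  labels <- rownames(W)
  N <- nrow(W)
  iu <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  pos <- w > 0
  iu <- iu[pos, , drop = FALSE]
  w <- w[pos]

  comp <- component_labels(N, iu)
  if (length(unique(comp)) > 1) {
    sizes <- table(comp)
    stop("positive-weight graph is disconnected: ", length(sizes),
         " components of sizes ", paste(sizes, collapse = ", "))
  }

  ord <- order(-w, iu[, 1], iu[, 2])
  iu <- iu[ord, , drop = FALSE]
  # Kruskal on descending weight = maximum-weight spanning tree
  parent <- seq_len(N)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  in_tree <- logical(nrow(iu))
  for (k in seq_len(nrow(iu))) {
    ra <- find(iu[k, 1]); rb <- find(iu[k, 2])
    if (ra != rb) {
      parent[ra] <- rb
      in_tree[k] <- TRUE
    }
  }
  keep <- in_tree
  m <- sum(keep)
  extra <- which(!in_tree)
  for (k in extra) {
    if (2 * m / N >= target_mean_degree) break
    keep[k] <- TRUE
    m <- m + 1
  }
  sel <- iu[keep, , drop = FALSE]
  cbind(labels[sel[, 1]], labels[sel[, 2]])
}

component_labels <- function(N, eidx) {
  g <- igraph::make_empty_graph(n = N, directed = FALSE)
  if (nrow(eidx)) g <- igraph::add_edges(g, t(eidx))
  igraph::components(g)$membership
}
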