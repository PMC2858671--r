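#' Louvain community detection, best of several runs
#'
#' Greedy modularity optimisation (local moves plus aggregation) at
#' resolution 1. The vertex order is permuted per run and the partition of
#' highest modularity `Q = sum_c [e_c/m - (d_c/2m)^2]` over `runs` seeded
#' runs is returned.
#'
#' @param net a [spatial_network()] or igraph graph with at least one edge.
#' @param runs number of seeded runs (default 20).
#' @param seed optional integer seed.
#' @return list with `membership` (integer vector named by node id) and `Q`.
#' @export
louvain_partition <- function(net, runs = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  if (igraph::ecount(g) == 0) stop("empty edge set")
  best <- NULL
  for (r in seq_len(runs)) {
    perm <- sample.int(igraph::vcount(g))
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    # vertex i of g is vertex perm[i] of gp
    mem <- as.integer(igraph::membership(cl))[perm]
    Q <- igraph::modularity(g, mem)
    if (is.null(best) || Q > best$Q) best <- list(membership = mem, Q = Q)
  }
  names(best$membership) <- igraph::V(g)$name
  best
}

#' Modularity significance against two null models
#'
#' Compares the observed modularity (best of `runs` Louvain runs) with the
#' modularity distribution of `n_null` pure-random surrogates (same N and m)
#' and `n_null` degree-preserving surrogates (Maslov-Sneppen, 15 accepted
#' swaps per edge), each scored by the identical Louvain procedure. The
#' one-tailed p-value is the upper-tail probability of the observed Q under
#' a t reference fitted to each null distribution,
#' `p = P(T_{n-1} > (Q_obs - mean_null) / sd_null)`, so a pure-random input
#' is flagged at rate ~alpha. If a null distribution degenerates (zero
#' variance) the exceedance count `(1 + #{Q_null >= Q_obs}) / (n + 1)` is
#' used instead and the result flagged.
#'
#' @param net a [spatial_network()] or igraph graph.
#' @param n_null surrogates per null model (default 100, minimum 10).
#' @param runs Louvain runs per network, observed and null alike (default 1;
#'   what matters for calibration is that the observed network and every
#'   surrogate are scored by the identical procedure).
#' @param seed optional integer seed.
#' @return list with `Q`, `p_func` (vs degree-preserving nulls), `p_rand`
#'   (vs pure-random nulls), the null Q vectors, and `degenerate` flags.
#' @export
modularity_significance <- function(net, n_null = 100, runs = 1,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_null < 10) stop("n_null must be at least 10")
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  N <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m < 1) stop("empty edge set")
  obs <- louvain_partition(g, runs = runs)

  eidx <- igraph::as_edgelist(g, names = FALSE)
  null_q <- function(make_g) {
    vapply(seq_len(n_null), function(i)
      louvain_partition(make_g(), runs = runs)$Q, 0)
  }
  q_rand <- null_q(function() igraph::sample_gnm(N, m))
  q_func <- null_q(function() {
    res <- maslov_rewire_core(eidx - 1L, N, ceiling(15 * m),
                              max(1000, 200 * ceiling(15 * m)))
    ge <- igraph::make_empty_graph(N, directed = FALSE)
    igraph::add_edges(ge, t(res$edges + 1L))
  })

  tail_p <- function(qs) {
    s <- stats::sd(qs)
    if (!is.finite(s) || s == 0) {
      list(p = (1 + sum(qs >= obs$Q)) / (n_null + 1), degenerate = TRUE)
    } else {
      z <- (obs$Q - mean(qs)) / s
      list(p = stats::pt(z, df = n_null - 1, lower.tail = FALSE),
           degenerate = FALSE)
    }
  }
  pr <- tail_p(q_rand)
  pf <- tail_p(q_func)
  list(Q = obs$Q, membership = obs$membership,
       p_func = pf$p, p_rand = pr$p,
       null_Q_func = q_func, null_Q_rand = q_rand,
       degenerate = c(func = pf$degenerate, rand = pr$degenerate))
}

#' Hierarchical modular decomposition with significance testing
#'
#' Recursively: partition the current module's induced subnetwork with
#' Louvain, test its modularity against degree-preserving and pure-random
#' null models matched to that subnetwork's own size (and degree sequence /
#' edge count respectively), and recurse into the submodules only where both
#' tests pass at level `alpha`. Modules smaller than `min_module_size`
#' become untested leaves. The depth of the returned tree is the number of
#' significant hierarchical levels: a non-modular network yields depth 1, a
#' flat modular network depth 2, modules-within-modules depth 3, and so on.
#'
#' @param net a [spatial_network()] or igraph graph.
#' @param alpha significance level for both tests (default 0.05).
#' @param min_module_size below this, modules are not tested (default 8).
#' @param n_null,runs passed to [modularity_significance()].
#' @param seed optional integer seed.
#' @return object of class `module_tree`: a nested list with fields
#'   `members`, `Q`, `p_func`, `p_rand`, `significant`, `depth` and
#'   `children`. `module_tree_depth()` extracts the depth.
#' @export
hierarchical_decompose <- function(net, alpha = 0.05, min_module_size = 8,
                                   n_null = 100, runs = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }

  decompose <- function(sub) {
    node <- list(members = igraph::V(sub)$name,
                 Q = NA_real_, p_func = NA_real_, p_rand = NA_real_,
                 significant = FALSE, children = list())
    n_sub <- igraph::vcount(sub)
    if (n_sub < min_module_size || igraph::ecount(sub) < 2) {
      node$depth <- 1L
      return(node)
    }
    sig <- modularity_significance(sub, n_null = n_null, runs = runs)
    node$Q <- sig$Q
    node$p_func <- sig$p_func
    node$p_rand <- sig$p_rand
    node$significant <- is.finite(sig$p_func) && is.finite(sig$p_rand) &&
      sig$p_func < alpha && sig$p_rand < alpha &&
      max(sig$membership) > 1
    if (!node$significant) {
      node$depth <- 1L
      return(node)
    }
    for (mod in split(seq_len(n_sub), sig$membership)) {
      child <- decompose(igraph::induced_subgraph(sub, mod))
      node$children[[length(node$children) + 1L]] <- child
    }
    node$depth <- 1L + max(vapply(node$children, `[[`, 0L, "depth"))
    node
  }

  tree <- decompose(g)
  class(tree) <- "module_tree"
  tree
}

#' @rdname hierarchical_decompose
#' @param tree a `module_tree`.
#' @export
module_tree_depth <- function(tree) tree$depth

#' @export
print.module_tree <- function(x, ...) {
  show <- function(node, indent) {
    cat(sprintf("%s%d nodes  Q=%s  p_func=%s  p_rand=%s%s\n",
                strrep("  ", indent), length(node$members),
                fmt(node$Q), fmt(node$p_func), fmt(node$p_rand),
                if (isTRUE(node$significant)) "  *" else ""))
    for (ch in node$children) show(ch, indent + 1)
  }
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3g", v)
  cat(sprintf("Module tree, depth %d\n", x$depth))
  show(x, 0)
  invisible(x)
}

#' Louvain-consensus co-classification matrix
#'
#' Runs seeded Louvain `runs` times; each run contributes its full
#' aggregation hierarchy, every hierarchical depth weighted equally, and
#' entry `(i, j)` is the average frequency with which nodes `i` and `j`
#' share a module. Rows are ordered by the leaf order of average-linkage
#' clustering of the matrix, which makes nested modules visible as blocks
#' along the diagonal. This consensus rendering is for visualisation; no
#' quantitative claim rests on it.
#'
#' @param net a [spatial_network()] or igraph graph.
#' @param runs number of Louvain runs (default 100, minimum 2).
#' @param seed optional integer seed.
#' @return object of class `coclass_matrix`: a symmetric N x N matrix of
#'   co-assignment frequencies with unit diagonal; the display permutation
#'   is in `attr(, "order")`.
#' @export
coclassification <- function(net, runs = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (runs < 2) stop("runs must be at least 2")
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  N <- igraph::vcount(g)
  acc <- matrix(0, N, N)
  for (r in seq_len(runs)) {
    perm <- sample.int(N)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    mems <- cl$memberships
    if (is.null(mems)) mems <- matrix(igraph::membership(cl), nrow = 1)
    run_acc <- matrix(0, N, N)
    for (lvl in seq_len(nrow(mems))) {
      mem <- mems[lvl, ][perm]
      run_acc <- run_acc + outer(mem, mem, `==`)
    }
    acc <- acc + run_acc / nrow(mems)
  }
  C <- acc / runs
  diag(C) <- 1
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(N))
  dimnames(C) <- list(ids, ids)
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  structure(C, order = hc$order, class = "coclass_matrix")
}

#' @export
print.coclass_matrix <- function(x, ...) {
  cat(sprintf("Co-classification matrix: %d nodes, mean off-diagonal %.3f\n",
              nrow(x), mean(x[upper.tri(x)])))
  invisible(x)
}

#' @export
plot.coclass_matrix <- function(x, ...) {
  ord <- attr(x, "order")
  graphics::image(unclass(x)[ord, rev(ord)], axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
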