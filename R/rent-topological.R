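#' Topological Rent exponent from recursive partitioning
#'
#' Fits the slope of `log(mean_e)` on `log(mean_n)` across partition levels
#' by weighted linear regression, each level weighted by its partition count.
#' With whole-network boundary counting the largest partitions sit in the
#' boundary-affected regime ("Region II") where the power law breaks down,
#' so the `exclude_top` largest usable levels are dropped before fitting and
#' the remaining levels are Region I. With parent-relative counting every
#' level records a genuine bisection cut and no saturation occurs, so by
#' default nothing is excluded.
#'
#' @param levels a `partition_levels` object from [recursive_partition()],
#'   or a data frame with columns `mean_n`, `mean_e`, `partition_count`.
#' @param exclude_top number of largest-partition levels to exclude as
#'   Region II. Default `NULL`: 2 for `boundary = "network"` partitions,
#'   0 for `boundary = "parent"` (level 0, whose boundary count is zero,
#'   is always excluded).
#' @return a [rent_fit()] object; the topological Rent exponent is
#'   `$exponent`.
#' @export
fit_topological_rent <- function(levels, exclude_top = NULL) {
  lv <- if (inherits(levels, "partition_levels")) attr(levels, "levels")
        else as.data.frame(levels)
  if (is.null(exclude_top)) {
    exclude_top <- if (identical(attr(levels, "boundary"), "network")) 2 else 0
  }
  lv <- lv[is.finite(lv$mean_e) & lv$mean_e > 0 & lv$mean_n > 0, , drop = FALSE]
  lv <- lv[order(-lv$mean_n), , drop = FALSE]
  if (exclude_top > 0 && nrow(lv) > exclude_top) {
    region <- c(rep(FALSE, exclude_top), rep(TRUE, nrow(lv) - exclude_top))
  } else {
    region <- rep(TRUE, nrow(lv))
  }
  if (sum(region) < 3) {
    stop("fewer than 3 usable levels in Region I; use a larger network")
  }
  rent_fit(lv$mean_n, lv$mean_e, weights = lv$partition_count,
           method = "wls", region = region)
}

#' Fractal topological dimension from the Rent exponent
#'
#' The topological dimension of a network with topological Rent exponent
#' `p_T` is `D_T = 1 / (1 - p_T)`; a D-dimensional lattice has `p_T = 1 -
#' 1/D` and hence `D_T = D`, while `p_T -> 1` signals unbounded dimension.
#' When given a [rent_fit()], the confidence interval of the exponent is
#' propagated through the same map.
#'
#' @param p_T topological Rent exponent in `[0, 1)`, or a [rent_fit()].
#' @return the dimension estimate; for a fit input, a vector with elements
#'   `D_T`, `lo`, `hi`.
#' @examples
#' topological_dimension(0.5) # a 2-D lattice
#' @export
topological_dimension <- function(p_T) {
  if (inherits(p_T, "rent_fit")) {
    ci <- pmax(unname(p_T$ci95), 0)
    # an interval endpoint at or above 1 maps to unbounded dimension
    ci_d <- ifelse(ci >= 1, Inf, 1 / (1 - ci))
    return(c(D_T = topological_dimension(p_T$exponent),
             lo = ci_d[1], hi = ci_d[2]))
  }
  if (any(p_T >= 1)) stop("p_T >= 1 implies infinite topological dimension")
  if (any(p_T < 0)) stop("p_T must be nonnegative")
  1 / (1 - p_T)
}

#' Box-counting estimate of the topological dimension
#'
#' Greedy renormalisation covering: for each topological box size `l_B`,
#' nodes are greedily grouped into boxes whose members all lie within
#' shortest-path distance `< l_B` of each other. The covering order places
#' hard-to-box nodes first (many conflicts, i.e. many nodes at distance
#' `>= l_B`), jittered over `n_orders` randomised orders, and the minimum
#' box count `N_B` is kept. The dimension is minus the slope of the
#' weighted regression of `log N_B` on `log l_B` (weights `N_B`). The fit
#' spans the scaling regime `2 <= l_B <= max(4, diameter/4)`: `l_B = 1` is
#' the trivial all-singletons covering, and boxes comparable to the network
#' extent saturate toward a single box (the covering analogue of the
#' boundary-affected Region II).
#'
#' @param net a connected [spatial_network()] with graph diameter >= 3.
#' @param n_orders randomised covering orders per box size (default 10).
#' @param seed optional integer seed.
#' @return list with `D` (dimension estimate), `fit` (the underlying lm) and
#'   `table` (`l_B`, `N_B`).
#' @export
box_counting_dimension <- function(net, n_orders = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(net)
  if (igraph::components(g)$no > 1) stop("network must be connected")
  dmat <- igraph::distances(g)
  diam <- max(dmat)
  if (diam < 3) stop("graph diameter < 3: insufficient scaling range")
  N <- n_nodes(net)

  cover_count <- function(lB, ord) {
    boxes <- list()
    for (v in ord) {
      placed <- FALSE
      if (length(boxes)) {
        for (b in seq_along(boxes)) {
          if (all(dmat[v, boxes[[b]]] < lB)) {
            boxes[[b]] <- c(boxes[[b]], v)
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) boxes[[length(boxes) + 1L]] <- v
    }
    length(boxes)
  }

  lBs <- 2:max(4, diam %/% 4)
  NB <- vapply(lBs, function(lB) {
    conflicts <- rowSums(dmat >= lB)
    min(vapply(seq_len(n_orders), function(i)
      cover_count(lB, order(-conflicts + stats::runif(N))), 0))
  }, 0)

  fit <- stats::lm(log(NB) ~ log(lBs), weights = NB)
  list(D = -unname(stats::coef(fit)[2]), fit = fit,
       table = data.frame(l_B = lBs, N_B = NB))
}

#' Compare power-law, exponential, linear and quadratic scaling models
#'
#' Fits `y = k x^p` (log-log linear), `y = a exp(b x)` (log-linear),
#' `y = a + b x` and `y = a + b x + c x^2`, then ranks them by the
#' small-sample-corrected information criterion (AICc) computed from the
#' residuals on the common untransformed scale, so the log-space fits are
#' not favoured by their transformed likelihoods.
#'
#' @param x,y positive numeric vectors, at least 5 points.
#' @return data frame ranked best-first with columns `model`, `aicc`, `rss`,
#'   `n_par`; ties are broken in favour of the simpler model.
#' @export
compare_scaling_models <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 5) stop("need at least 5 points")
  if (any(x <= 0) || any(y <= 0)) {
    stop("x and y must be positive for the log transforms")
  }
  n <- length(x)
  preds <- list(
    linear = {
      f <- stats::lm(y ~ x); list(p = stats::fitted(f), k = 2)
    },
    power = {
      f <- stats::lm(log(y) ~ log(x))
      list(p = exp(stats::fitted(f)), k = 2)
    },
    exponential = {
      f <- stats::lm(log(y) ~ x)
      list(p = exp(stats::fitted(f)), k = 2)
    },
    quadratic = {
      f <- stats::lm(y ~ x + I(x^2)); list(p = stats::fitted(f), k = 3)
    })
  scale_y <- sum(y^2)
  aicc_of <- function(rss, k) {
    # a numerically exact fit ties at -Inf; simplicity order then decides
    if (rss <= 1e-16 * scale_y) return(-Inf)
    k_full <- k + 1 # + error variance
    denom <- n - k_full - 1
    base <- n * log(rss / n) + 2 * k_full
    if (denom > 0) base + 2 * k_full * (k_full + 1) / denom else Inf
  }
  tab <- do.call(rbind, lapply(names(preds), function(nm) {
    rss <- sum((y - preds[[nm]]$p)^2)
    data.frame(model = nm, aicc = aicc_of(rss, preds[[nm]]$k), rss = rss,
               n_par = preds[[nm]]$k)
  }))
  # simplicity order breaks exact ties (linear before power before the rest)
  tab <- tab[order(round(tab$aicc, 8), seq_len(nrow(tab))), ]
  rownames(tab) <- NULL
  tab
}
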