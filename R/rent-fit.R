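#' Fit Rent's rule to an (n, e) scatter
#'
#' Rent's rule is the power law `e = k * n^p` between the number of nodes `n`
#' in a block and the number of connections `e` crossing the block boundary.
#' The exponent is estimated as the slope of `log e` on `log n`, either by
#' (weighted) least squares or by robust iteratively reweighted least squares
#' with a bisquare loss (`MASS::rlm`), which is the default for noisy box
#' scatters.
#'
#' @param n,e positive numeric vectors (block node and boundary-edge counts).
#' @param weights optional per-point weights for the `"wls"` method.
#' @param method `"irls"` (robust bisquare IRLS) or `"wls"` (weighted or
#'   ordinary least squares).
#' @param region optional logical mask selecting the points that enter the
#'   fit (Region I); excluded points are kept in the object for plotting.
#' @return object of class `rent_fit` with components `exponent`, `ci95`,
#'   `coefficient_k`, `se`, `region_mask`, `fit_diagnostics` (r.squared and
#'   residuals on the log scale), `data`, and `method`.
#' @seealso [fit_topological_rent()], [fit_physical_rent()]
#' @examples
#' s <- make_powerlaw_scatter(k = 2, p = 0.6, noise_sd = 0.05, seed = 1)
#' fit <- rent_fit(s$n, s$e)
#' coef(fit)
#' @export
rent_fit <- function(n, e, weights = NULL, method = c("irls", "wls"),
                     region = NULL) {
  method <- match.arg(method)
  n <- as.numeric(n); e <- as.numeric(e)
  if (length(n) != length(e)) stop("n and e differ in length")
  if (is.null(region)) region <- rep(TRUE, length(n))
  usable <- region & is.finite(n) & is.finite(e) & n > 0 & e > 0
  if (sum(usable) < 3) stop("need at least 3 usable (n, e) points")
  ln <- log(n[usable]); le <- log(e[usable])
  w <- if (is.null(weights)) NULL else weights[usable]

  if (method == "irls") {
    fit <- suppressWarnings(
      MASS::rlm(le ~ ln, psi = MASS::psi.bisquare, maxit = 50))
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  } else {
    fit <- if (is.null(w)) stats::lm(le ~ ln) else
      stats::lm(le ~ ln, weights = w)
    cf <- stats::coef(fit)
    # vcov warns on numerically exact fits; a zero se is the right answer
    se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  }
  df <- length(ln) - 2
  tq <- stats::qt(0.975, max(df, 1))
  p_hat <- unname(cf[2])
  res <- stats::residuals(fit)
  ss_tot <- sum((le - stats::weighted.mean(le, if (is.null(w)) rep(1, length(le)) else w))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1

  structure(list(
    exponent = p_hat,
    ci95 = unname(c(p_hat - tq * se[2], p_hat + tq * se[2])),
    coefficient_k = exp(unname(cf[1])),
    se = unname(se[2]),
    region_mask = usable,
    fit_diagnostics = list(r.squared = r2, residuals = res, df = df),
    data = data.frame(n = n, e = e),
    method = method), class = "rent_fit")
}

#' @export
print.rent_fit <- function(x, ...) {
  cat(sprintf("Rent fit (%s): p = %.4f  95%% CI [%.4f, %.4f],  k = %.4g\n",
              x$method, x$exponent, x$ci95[1], x$ci95[2], x$coefficient_k))
  cat(sprintf("  %d of %d points in the fitted region, R^2 = %.3f\n",
              sum(x$region_mask), nrow(x$data), x$fit_diagnostics$r.squared))
  invisible(x)
}

#' @export
summary.rent_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  log-scale residual SD: %.4f\n",
              stats::sd(object$fit_diagnostics$residuals)))
  invisible(object)
}

#' @export
coef.rent_fit <- function(object, ...) {
  c(k = object$coefficient_k, p = object$exponent)
}

#' @export
predict.rent_fit <- function(object, newdata = NULL, ...) {
  n <- if (is.null(newdata)) object$data$n else
    if (is.data.frame(newdata)) newdata$n else as.numeric(newdata)
  object$coefficient_k * n^object$exponent
}

#' @export
plot.rent_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$n, d$e, log = "xy", pch = ifelse(x$region_mask, 16, 1),
                 cex = 0.6, xlab = "n (nodes in block)",
                 ylab = "e (boundary edges)", ...)
  nn <- exp(seq(log(min(d$n[d$n > 0])), log(max(d$n)), length.out = 50))
  graphics::lines(nn, predict(x, nn), col = 2, lwd = 2)
  invisible(x)
}
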