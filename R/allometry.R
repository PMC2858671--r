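#' Convert between the allometric exponent and the Rent exponent
#'
#' Across mammalian species, white-matter volume scales allometrically with
#' gray-matter volume, `Vw ~ Vg^a`. Approximating the brain as a sphere,
#' the white-matter cross-sectional area scales as `A ~ Vw^(2/3)`; with a
#' constant number of connections per unit area (`e = sigma * A`) and a
#' constant density of processing elements per unit gray-matter volume
#' (`n = rho * Vg`), Rent's rule `e = k n^p` forces `a = (3/2) p`, i.e.
#' `p = (2/3) a`. The constants `sigma` and `rho` cancel in the exponent
#' relation and never appear numerically.
#'
#' @param a allometric scaling exponent (> 0).
#' @return `allometric_to_rent`: the implied Rent exponent `p = (2/3) a`.
#' @examples
#' allometric_to_rent(1)    # isometric case: p = 2/3
#' rent_to_allometric(2/3)  # and back: a = 1
#' @export
allometric_to_rent <- function(a) {
  if (any(a <= 0)) stop("a must be positive")
  (2 / 3) * a
}

#' @rdname allometric_to_rent
#' @param p physical Rent exponent in (0, 1), or a [rent_fit()] whose
#'   confidence interval is propagated linearly.
#' @return `rent_to_allometric`: the implied allometric exponent
#'   `a = (3/2) p` (for a fit input, a vector `a`, `lo`, `hi`).
#' @export
rent_to_allometric <- function(p) {
  if (inherits(p, "rent_fit")) {
    return(c(a = 1.5 * p$exponent, lo = 1.5 * p$ci95[1],
             hi = 1.5 * p$ci95[2]))
  }
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  1.5 * p
}

#' Fit the allometric exponent from volume pairs
#'
#' Ordinary least squares of `log Vw` on `log Vg`; the slope is the
#' allometric exponent `a`.
#'
#' @param Vg,Vw positive gray- and white-matter volumes (same units), or a
#'   data frame with columns `Vg` and `Vw` as the first argument.
#' @return list with `a`, `ci95`, `intercept` and the underlying `lm` fit.
#' @export
fit_allometric <- function(Vg, Vw = NULL) {
  if (is.data.frame(Vg)) {
    Vw <- Vg$Vw
    Vg <- Vg$Vg
  }
  if (any(Vg <= 0) || any(Vw <= 0)) stop("volumes must be positive")
  if (length(Vg) < 2) stop("need at least 2 volume pairs")
  fit <- stats::lm(log(Vw) ~ log(Vg))
  a <- unname(stats::coef(fit)[2])
  # confint warns on numerically exact fits; a zero-width interval is right
  ci <- if (length(Vg) > 2)
    unname(suppressWarnings(stats::confint(fit))[2, ]) else c(a, a)
  list(a = a, ci95 = ci, intercept = unname(stats::coef(fit)[1]),
       fit = fit)
}

#' Predict white-matter volume from a Rent exponent
#'
#' The predicted allometric curve `Vw(Vg) = Vw0 * (Vg / Vg0)^((3/2) p)`
#' anchored so it passes exactly through the reference pair
#' `(Vg0, Vw0)`.
#'
#' @param Vg gray-matter volumes at which to predict.
#' @param p physical Rent exponent in (0, 1).
#' @param anchor list or data frame row with positive elements `Vg` and
#'   `Vw` that the curve must pass through.
#' @return predicted white-matter volumes.
#' @export
predict_white_matter <- function(Vg, p, anchor) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (anchor$Vg <= 0 || anchor$Vw <= 0) stop("anchor volumes must be positive")
  anchor$Vw * (Vg / anchor$Vg)^(1.5 * p)
}
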