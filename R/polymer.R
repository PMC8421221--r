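## Closed-form polymer statistics: Gaussian chain and the stiff-polymer
## worm-like chain (WLC) end-to-end distribution, with free energies and
## forces derived from them.

#' Gaussian-chain specification
#'
#' Parameter set of a flexible Gaussian polymer: `n` Kuhn segments of length
#' `b` (nm).  The end-to-end vector is trivariate normal with variance
#' `n b^2`; the chain models short flexible linkages (ssDNA overhangs plus a
#' biotin--neutravidin joint, lumped together).
#'
#' @param n segment count (> 0, need not be an integer).
#' @param b Kuhn length in nm (> 0).
#' @return An object of class `gaussian_chain`.
#' @examples
#' gaussian_chain(n = 4, b = 1.5)
#' @export
gaussian_chain <- function(n, b) {
  stop_if_not_positive(n, "n")
  stop_if_not_positive(b, "b")
  structure(list(n = n, b = b), class = "gaussian_chain")
}

#' @export
print.gaussian_chain <- function(x, ...) {
  cat(sprintf("Gaussian chain: n = %g segments, b = %g nm (RMS EED %.3g nm)\n",
              x$n, x$b, sqrt(x$n) * x$b))
  invisible(x)
}

#' Thermal energy scale
#'
#' @param kBT thermal energy in pN nm.  The default 4.114 pN nm corresponds
#'   to T = 298 K.
#' @return An object of class `thermal_scale`.
#' @export
thermal_scale <- function(kBT = 4.114) {
  stop_if_not_positive(kBT, "kBT")
  structure(list(kBT = kBT), class = "thermal_scale")
}

#' @export
print.thermal_scale <- function(x, ...) {
  cat(sprintf("Thermal scale: kBT = %g pN nm\n", x$kBT))
  invisible(x)
}

#' Gaussian-chain end-to-end distance density
#'
#' Probability density (per nm^3) of the end-to-end *vector* of a Gaussian
#' chain evaluated at scalar separation `R`:
#' `p(R) = (3 / (2 pi n b^2))^{3/2} exp(-3 R^2 / (2 n b^2))`.
#' The density of the scalar distance is `p(R) * 4 pi R^2`.
#'
#' @param R end-to-end distance(s) in nm, `R >= 0`.
#' @param chain a [gaussian_chain()].
#' @return Numeric vector of densities (nm^-3).
#' @examples
#' ch <- gaussian_chain(4, 1.5)
#' integrate(function(R) gaussian_eed_pdf(R, ch) * 4 * pi * R^2, 0, Inf)$value
#' @export
gaussian_eed_pdf <- function(R, chain) {
  stopifnot(inherits(chain, "gaussian_chain"))
  if (any(R < 0)) stop("`R` must be non-negative", call. = FALSE)
  v <- chain$n * chain$b^2
  (3 / (2 * pi * v))^(3 / 2) * exp(-3 * R^2 / (2 * v))
}

#' Worm-like chain specification (stiff-polymer regime)
#'
#' Contour length `Lc` and persistence length `lp`, both in nm.  The
#' end-to-end distribution uses the stiff-polymer closed form (Frey's
#' formula), which is accurate when `lp/Lc` is not much smaller than 1.  The
#' normalization constant of the density over (0, Lc) is computed once by
#' adaptive quadrature and cached in the object.
#'
#' @param Lc contour length in nm (> 0).
#' @param lp persistence length in nm (> 0).
#' @return An object of class `wlc` with the cached normalization constant.
#' @examples
#' wlc(Lc = 85, lp = 50)
#' @export
wlc <- function(Lc, lp) {
  stop_if_not_positive(Lc, "Lc")
  stop_if_not_positive(lp, "lp")
  if (lp / Lc < 0.1)
    warning("lp/Lc < 0.1: outside the stiff-polymer regime of the closed form",
            call. = FALSE)
  spec <- structure(list(Lc = Lc, lp = lp, norm = 1), class = "wlc")
  spec$norm <- integrate(function(R) wlc_frey_pdf(R, spec, normalized = FALSE),
                         0, Lc, rel.tol = 1e-10,
                         subdivisions = 400L)$value
  spec
}

#' @export
print.wlc <- function(x, ...) {
  cat(sprintf("Worm-like chain: Lc = %g nm, lp = %g nm (lp/Lc = %.3g)\n",
              x$Lc, x$lp, x$lp / x$Lc))
  invisible(x)
}

## Frey stiff-polymer scaling function f(x).  Two series branches matched at
## x = 0.2; each keeps three terms.  x = (lp/Lc) (1 - R/Lc).
frey_scaling <- function(x) {
  out <- numeric(length(x))
  hi <- x > 0.2
  if (any(hi)) {
    xh <- x[hi]
    out[hi] <- (pi / 2) * (exp(-pi^2 * xh) -
                           4 * exp(-4 * pi^2 * xh) +
                           9 * exp(-9 * pi^2 * xh))
  }
  lo <- !hi & x > 0
  if (any(lo)) {
    xl <- x[lo]
    out[lo] <- 1 / (8 * (pi * xl)^(3 / 2)) *
      ((1 / xl - 2) * exp(-1 / (4 * xl)) +
       (9 / xl - 2) * exp(-9 / (4 * xl)) +
       (25 / xl - 2) * exp(-25 / (4 * xl)))
  }
  out
}

#' Stiff-polymer WLC end-to-end distance density
#'
#' Closed-form density (per nm) of the scalar end-to-end distance of a
#' worm-like chain in the stiff regime:
#' `p(R) = (lp / (N Lc^2)) f(x)` with `x = (lp/Lc)(1 - R/Lc)` and `f` a
#' three-term series with branches switched at `x = 0.2`.  `N` normalizes the
#' density to unit integral over (0, Lc); it is cached in the [wlc()] object.
#' The density is treated as one-dimensional in the scalar distance (no
#' additional `R^2` Jacobian).
#'
#' @param R end-to-end distance(s) in nm; density is 0 for `R >= Lc`,
#'   negative `R` is an error.
#' @param spec a [wlc()].
#' @param normalized if `FALSE`, the raw (unnormalized) expression is
#'   returned; used internally to compute the cached constant.
#' @return Numeric vector of densities (nm^-1).
#' @examples
#' w <- wlc(85, 50)
#' integrate(function(R) wlc_frey_pdf(R, w), 0, 85)$value  # 1
#' @export
wlc_frey_pdf <- function(R, spec, normalized = TRUE) {
  stopifnot(inherits(spec, "wlc"))
  if (any(R < 0)) stop("`R` must be non-negative", call. = FALSE)
  x <- (spec$lp / spec$Lc) * (1 - R / spec$Lc)
  dens <- spec$lp / spec$Lc^2 * frey_scaling(x)
  dens[R >= spec$Lc] <- 0
  if (normalized) dens / spec$norm else dens
}

## Mode of the Frey density, cached lazily via environment attached at first
## use would complicate the plain-list class; an optimize() call is cheap.
wlc_mode <- function(spec) {
  optimize(function(R) wlc_frey_pdf(R, spec),
           interval = c(spec$Lc * 1e-4, spec$Lc * (1 - 1e-9)),
           maximum = TRUE, tol = 1e-10)$maximum
}

#' WLC free energy of extension
#'
#' `G(R) = -kBT ln p(R)` from the normalized stiff-polymer density, shifted
#' so that the minimum (at the density mode) is zero.
#'
#' @param R end-to-end distance(s) in nm, strictly inside (0, Lc).
#' @param spec a [wlc()].
#' @param thermal a [thermal_scale()].
#' @return Free energy in pN nm, >= 0 with equality at the density mode.
#' @export
wlc_free_energy <- function(R, spec, thermal = thermal_scale()) {
  stopifnot(inherits(spec, "wlc"), inherits(thermal, "thermal_scale"))
  if (any(R <= 0 | R >= spec$Lc))
    stop("`R` must lie strictly inside (0, Lc)", call. = FALSE)
  pmode <- wlc_frey_pdf(wlc_mode(spec), spec)
  -thermal$kBT * log(wlc_frey_pdf(R, spec) / pmode)
}

#' Compressive force borne by a WLC at a given end-to-end distance
#'
#' `F = -dG/dR` by a centered finite difference on [wlc_free_energy()].
#' Positive values are the compressive load carried by the chain (the free
#' energy decreases as the chain relaxes towards its preferred extension).
#' On the deeply compressed side the force plateaus at
#' `pi^2 lp kBT / Lc^2`.
#'
#' @param R end-to-end distance(s) in nm; `R - step` and `R + step` must stay
#'   inside (0, Lc).
#' @param spec a [wlc()].
#' @param thermal a [thermal_scale()].
#' @param step finite-difference half-step in nm (default 0.1).
#' @return Force in pN (positive = compressive below the mode).
#' @examples
#' wlc_compression_force(49, wlc(85, 50))  # ~0.28 pN
#' @export
wlc_compression_force <- function(R, spec, thermal = thermal_scale(),
                                  step = 0.1) {
  stopifnot(inherits(spec, "wlc"))
  stop_if_not_positive(step, "step")
  if (any(R - step <= 0 | R + step >= spec$Lc))
    stop("finite-difference stencil leaves (0, Lc); reduce `step` or move `R`",
         call. = FALSE)
  -(wlc_free_energy(R + step, spec, thermal) -
    wlc_free_energy(R - step, spec, thermal)) / (2 * step)
}

#' Contour length of B-form dsDNA
#'
#' @param bp base-pair count (> 0).
#' @param rise_per_bp helical rise in nm per bp (default 0.34).
#' @return Contour length in nm.
#' @examples
#' contour_length(249)  # 84.66 nm, the 249 bp test sample
#' @export
contour_length <- function(bp, rise_per_bp = 0.34) {
  if (any(!is.finite(bp) | bp <= 0))
    stop("`bp` must be positive", call. = FALSE)
  stop_if_not_positive(rise_per_bp, "rise_per_bp")
  bp * rise_per_bp
}
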