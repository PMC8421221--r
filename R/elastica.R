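## Euler elastica mechanics of the compressed dsDNA sample: critical
## buckling load and post-buckling force versus end-to-end distance via
## complete elliptic integrals.

#' Elastica (slender elastic rod) specification
#'
#' A rod of length `Lc` with bending rigidity `EI`.  For dsDNA the rigidity
#' is the persistence length times the thermal energy, `EI = lp kBT`; the
#' helper signature accepts either `EI` directly or `(lp, thermal)`.
#'
#' @param Lc rod length in nm.
#' @param EI bending rigidity in pN nm^2.  If missing, computed as
#'   `lp * thermal$kBT`.
#' @param lp persistence length in nm (used only when `EI` is missing).
#' @param thermal a [thermal_scale()] (used only when `EI` is missing).
#' @param boundary `"pinned"` (hinged ends, free to rotate, the default for
#'   biotin--neutravidin end linkages) or `"clamped"`.
#' @return An object of class `elastica_spec`.
#' @examples
#' elastica_spec(Lc = 85, lp = 50)
#' @export
elastica_spec <- function(Lc, EI = NULL, lp = NULL,
                          thermal = thermal_scale(),
                          boundary = c("pinned", "clamped")) {
  boundary <- match.arg(boundary)
  stop_if_not_positive(Lc, "Lc")
  if (is.null(EI)) {
    if (is.null(lp)) stop("supply either `EI` or `lp`", call. = FALSE)
    EI <- lp * thermal$kBT
  }
  stop_if_not_positive(EI, "EI")
  structure(list(Lc = Lc, EI = EI, boundary = boundary),
            class = "elastica_spec")
}

#' @export
print.elastica_spec <- function(x, ...) {
  cat(sprintf("Elastica: Lc = %g nm, EI = %g pN nm^2, %s-%s ends\n",
              x$Lc, x$EI, x$boundary, x$boundary))
  invisible(x)
}

#' Euler critical buckling force
#'
#' Onset of lateral bending under axial compression:
#' `pi^2 EI / Lc^2` for pinned-pinned ends, `4 pi^2 EI / Lc^2` for
#' clamped-clamped.
#'
#' @param spec an [elastica_spec()].
#' @return Force in pN.
#' @examples
#' euler_critical_force(elastica_spec(85, lp = 50))  # ~0.28 pN
#' @export
euler_critical_force <- function(spec) {
  stopifnot(inherits(spec, "elastica_spec"))
  mult <- if (spec$boundary == "clamped") 4 else 1
  mult * pi^2 * spec$EI / spec$Lc^2
}

#' Post-buckling force of a compressed elastica
#'
#' Solves the large-deflection (post-buckling) equilibrium of the rod at a
#' prescribed end-to-end distance.  For pinned-pinned ends the shortening
#' fixes the elliptic modulus `k` through
#' `end_to_end / Lc = 2 E(k) / K(k) - 1` and the axial force is
#' `F = 4 K(k)^2 EI / Lc^2`, with `K` and `E` the complete elliptic
#' integrals of the first and second kind.  As `end_to_end -> Lc` the force
#' tends continuously to the Euler critical load.  Clamped-clamped ends
#' satisfy the same shortening relation with a quadrupled force.
#'
#' @param end_to_end end-to-end distance(s) in nm, strictly inside (0, Lc).
#' @param spec an [elastica_spec()].
#' @param tol relative tolerance of the modulus root-finding.
#' @return Force(s) in pN (compressive load on the rod).
#' @examples
#' postbuckling_force(49, elastica_spec(85, lp = 50))  # ~0.36 pN
#' @export
postbuckling_force <- function(end_to_end, spec, tol = 1e-8) {
  stopifnot(inherits(spec, "elastica_spec"))
  if (any(end_to_end <= 0 | end_to_end >= spec$Lc))
    stop("`end_to_end` must lie strictly inside (0, Lc): the rod is unbuckled at or beyond Lc",
         call. = FALSE)
  mult <- if (spec$boundary == "clamped") 4 else 1
  vapply(end_to_end, function(e) {
    ratio <- e / spec$Lc
    f <- function(m) {
      ek <- pracma::ellipke(m)
      2 * ek$e / ek$k - 1 - ratio
    }
    m <- uniroot(f, c(1e-300, 1 - 1e-12), tol = tol * 1e-4)$root
    K <- pracma::ellipke(m)$k
    mult * 4 * K^2 * spec$EI / spec$Lc^2
  }, numeric(1))
}
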