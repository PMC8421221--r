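## Hinge + polymer-sample coupling: predict the angle distribution of a
## device with an incorporated sample held between two flexible linkers, by
## discretized integration over the linker configurations, and extract the
## force on the sample.

#' Hinge geometry
#'
#' @param arm_length arm length L from vertex to tip, nm (default 61).
#' @param attachment_radius radial position where the sample binds, nm
#'   (default: the arm tip, `arm_length`).
#' @return An object of class `hinge_geometry`.
#' @export
hinge_geometry <- function(arm_length = 61, attachment_radius = arm_length) {
  stop_if_not_positive(arm_length, "arm_length")
  stop_if_not_positive(attachment_radius, "attachment_radius")
  if (attachment_radius > arm_length)
    stop("`attachment_radius` cannot exceed `arm_length`", call. = FALSE)
  structure(list(arm_length = arm_length,
                 attachment_radius = attachment_radius),
            class = "hinge_geometry")
}

#' @export
print.hinge_geometry <- function(x, ...) {
  cat(sprintf("Hinge geometry: arm length %g nm, sample attached at %g nm\n",
              x$arm_length, x$attachment_radius))
  invisible(x)
}

#' Tip-to-tip chord distance at a hinge angle
#'
#' The straight-line separation of the two sample attachment points:
#' `2 r sin(theta/2)` with `r` the attachment radius.  At the arm tips of
#' the 61-nm device this gives 82 nm for the 85-degree peak angle.
#'
#' @param theta hinge angle(s) in degrees, in \[0, 180\].
#' @param geometry a [hinge_geometry()].
#' @return Distance(s) in nm.
#' @examples
#' chord_distance(85, hinge_geometry(61))
#' @export
chord_distance <- function(theta, geometry = hinge_geometry()) {
  stopifnot(inherits(geometry, "hinge_geometry"))
  if (any(theta < 0 | theta > 180))
    stop("`theta` must lie in [0, 180] degrees", call. = FALSE)
  2 * geometry$attachment_radius * sin(deg2rad(theta) / 2)
}

#' Coupled hinge + linkers + sample system
#'
#' Bundles the ingredients of the coupling model: the free-device angle
#' distribution (the hinge prior), one Gaussian-chain linker per arm tip,
#' the worm-like-chain sample spanning them, the hinge geometry, and the
#' spherical-grid spacing used to discretize the linker configuration
#' integral.
#'
#' @param hinge_dist an `angular_distribution`: the free device's angle
#'   distribution.
#' @param linker1,linker2 [gaussian_chain()] linkers (6-nt overhang plus
#'   biotin--neutravidin, lumped).
#' @param sample a [wlc()] describing the incorporated dsDNA.
#' @param geometry a [hinge_geometry()].
#' @param grid_spacing spherical-grid spacing Delta R in nm (default 2).
#' @return An object of class `coupled_system`.
#' @export
coupled_system <- function(hinge_dist, linker1, linker2, sample,
                           geometry = hinge_geometry(), grid_spacing = 2) {
  stopifnot(inherits(hinge_dist, "angular_distribution"),
            inherits(linker1, "gaussian_chain"),
            inherits(linker2, "gaussian_chain"),
            inherits(sample, "wlc"),
            inherits(geometry, "hinge_geometry"))
  stop_if_not_positive(grid_spacing, "grid_spacing")
  structure(list(hinge_dist = hinge_dist, linker1 = linker1,
                 linker2 = linker2, sample = sample, geometry = geometry,
                 grid_spacing = grid_spacing),
            class = "coupled_system")
}

#' @export
print.coupled_system <- function(x, ...) {
  cat("Coupled hinge-linker-sample system\n")
  print(x$geometry); print(x$linker1); print(x$linker2); print(x$sample)
  cat(sprintf("  grid spacing %g nm\n", x$grid_spacing))
  invisible(x)
}

## Spherical grid over one linker's end-to-end vector: points (x, y, z) and
## quadrature weights p(R) R^2 sin(theta) dR dtheta dphi, with per-shell
## angular spacings dtheta = dR/R, dphi = dR/(R sin theta) so the cells are
## approximately cubes of side dR.  Radial support is (0, n b), the grid
## limit of the model.  A chain whose full extent n b is below half a cell
## degenerates to a point linker at the origin.
linker_grid <- function(chain, dR) {
  nb <- chain$n * chain$b
  if (nb <= dR / 2)                        # point linker
    return(list(xyz = matrix(0, 1, 3), w = 1))
  Rs <- seq(dR / 2, nb, by = dR)
  Rs <- Rs[Rs < nb]
  if (length(Rs) == 0L)
    return(list(xyz = matrix(0, 1, 3), w = 1))
  pts <- list(); wts <- list(); idx <- 1L
  for (R in Rs) {
    ntheta <- max(1L, round(pi * R / dR))
    dth <- pi / ntheta
    for (j in seq_len(ntheta)) {
      th <- (j - 0.5) * dth
      nphi <- max(1L, round(2 * pi * R * sin(th) / dR))
      dph <- 2 * pi / nphi
      ph <- (seq_len(nphi) - 0.5) * dph
      pts[[idx]] <- cbind(R * sin(th) * cos(ph),
                          R * sin(th) * sin(ph),
                          rep(R * cos(th), nphi))
      wts[[idx]] <- rep(gaussian_eed_pdf(R, chain) * R^2 * sin(th) *
                          dR * dth * dph, nphi)
      idx <- idx + 1L
    }
  }
  list(xyz = do.call(rbind, pts), w = unlist(wts))
}

## All pairwise sums of the two linker grids: matrix S (one row per pair of
## grid points) and combined weights.  This is the discretized double
## integral over both linker configurations.
linker_pair_sums <- function(spec) {
  g1 <- linker_grid(spec$linker1, spec$grid_spacing)
  g2 <- linker_grid(spec$linker2, spec$grid_spacing)
  n1 <- nrow(g1$xyz); n2 <- nrow(g2$xyz)
  i <- rep(seq_len(n1), times = n2)
  j <- rep(seq_len(n2), each = n1)
  list(S = g1$xyz[i, , drop = FALSE] + g2$xyz[j, , drop = FALSE],
       w = g1$w[i] * g2$w[j])
}

#' Predicted angle distribution of a hinge with an incorporated sample
#'
#' For each hinge-angle bin the free-device probability is reweighted by the
#' configurational integral over the two Gaussian linkers and the WLC
#' sample: linker end-to-end vectors are enumerated on a spherical grid
#' (spacing `grid_spacing`, angular spacings chosen so cells are
#' approximately cubic, radial support (0, n b)), and for each pair of
#' linker vectors the sample's end-to-end vector is fixed by vector closure
#' against the tip-to-tip chord `2 L sin(theta/2)`.  The sample density is
#' evaluated at that closure distance (zero at or beyond the contour
#' length).  The result is renormalized to integrate to 1 over degrees.
#'
#' @param spec a [coupled_system()].
#' @return An `angular_distribution` on the hinge prior's bins.
#' @export
predict_coupled_angle_distribution <- function(spec) {
  stopifnot(inherits(spec, "coupled_system"))
  ps <- linker_pair_sums(spec)
  prior <- spec$hinge_dist
  mass <- numeric(length(prior$mids))
  for (k in seq_along(prior$mids)) {
    if (prior$density[k] <= 0) next
    d <- chord_distance(prior$mids[k], spec$geometry)
    ## chord vector along +z; closure: R_D = chord - Rp1 - Rp2
    RD <- sqrt(ps$S[, 1]^2 + ps$S[, 2]^2 + (d - ps$S[, 3])^2)
    mass[k] <- prior$density[k] * sum(ps$w * wlc_frey_pdf(RD, spec$sample))
  }
  if (all(mass == 0))
    stop("closure infeasible at every angle: predicted distribution is zero",
         call. = FALSE)
  widths <- diff(prior$bin_edges)
  angular_distribution(prior$bin_edges, mass / sum(mass * widths))
}

#' Free energy and force of the coupled system
#'
#' Boltzmann-inverts the predicted coupled distribution,
#' `G(theta) = -kBT ln P(theta)` (minimum shifted to zero), and converts the
#' angular derivative into the force on the sample through the chord rule
#' `dr/dtheta = r_att cos(theta/2)`:
#' `F(theta) = -(dG/dtheta) / (dr/dtheta)`.  The sign follows
#' [wlc_compression_force()]: below the preferred extension `F` is positive
#' and equals the compressive load borne by the sample; on the extension
#' side it is negative (tension).  Derivatives are centered finite
#' differences on the bin grid.
#'
#' @param spec a [coupled_system()].
#' @param thermal a [thermal_scale()].
#' @param distribution optionally, a precomputed result of
#'   [predict_coupled_angle_distribution()] for the same spec.
#' @return An object of class `coupled_profile` with `theta` (deg), `G`
#'   (pN nm), `force` (pN; `NA` at the two edge bins), and the distribution.
#' @export
coupled_free_energy_and_force <- function(spec, thermal = thermal_scale(),
                                          distribution = NULL) {
  stopifnot(inherits(spec, "coupled_system"))
  dist <- distribution %||% predict_coupled_angle_distribution(spec)
  pos <- dist$density > 0
  if (any(!pos[seq(which(pos)[1], max(which(pos)))]))
    warning("zero-density bins inside the support were excluded", call. = FALSE)
  theta <- dist$mids[pos]
  G <- -thermal$kBT * log(dist$density[pos])
  G <- G - min(G)
  n <- length(theta)
  force <- rep(NA_real_, n)
  if (n >= 3L) {
    th_rad <- deg2rad(theta)
    dGdth <- (G[-(1:2)] - G[1:(n - 2)]) / (th_rad[-(1:2)] - th_rad[1:(n - 2)])
    drdth <- spec$geometry$attachment_radius * cos(th_rad[2:(n - 1)] / 2)
    force[2:(n - 1)] <- -dGdth / drdth
  }
  structure(list(theta = theta, G = G, force = force, distribution = dist,
                 kBT = thermal$kBT),
            class = "coupled_profile")
}

#' @export
print.coupled_profile <- function(x, ...) {
  cat(sprintf("Coupled profile: [%.1f, %.1f] deg; force range [%.3g, %.3g] pN\n",
              min(x$theta), max(x$theta),
              min(x$force, na.rm = TRUE), max(x$force, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
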