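## Nucleosome unwrapping in a hinge device: tangent-line spool geometry,
## a pluggable per-bp adhesion energy, and the partition-function prediction
## of unwrapping distributions and constrained device angles.

#' Nucleosome + construct specification
#'
#' Geometry and energetics of a nucleosome on a DNA construct spanning the
#' hinge arms.  The paper-grade construct is 249 bp total: 147 bp wrapped
#' around the histone core plus 51 bp of free linker on each side.  The
#' wrapped DNA follows a superhelix (canonical crystallographic values:
#' radius 4.18 nm, 1.67 turns, pitch 2.39 nm); unwrapped DNA leaves along
#' the tangent at the last point of contact.
#'
#' The unwrapping free energy is a piecewise-constant per-bp net adhesion:
#' each base pair released from an end costs `gamma_outer` kBT while within
#' the first `outer_turn_bp` from that end (the outer wrap, weakly bound)
#' and `gamma_inner` kBT beyond it.  The fully wrapped state is the zero of
#' energy.  These parameters are a documented calibration, not a fit:
#' absolute unwrapping totals depend on them.
#'
#' @param total_bp total construct length in bp (default 249).
#' @param wrapped_bp bp wrapped in the fully wrapped state (default 147).
#' @param linker_bp free linker bp per side (default 51).
#' @param superhelix_radius superhelix radius in nm (default 4.18).
#' @param superhelix_turns wrap turns in the fully wrapped state (1.67).
#' @param superhelix_pitch superhelix pitch in nm per turn (2.39); only the
#'   `"helix"` backend uses it.
#' @param rise_per_bp helical rise, nm/bp (0.34).
#' @param gamma_outer,gamma_inner per-bp adhesion free energy, kBT
#'   (defaults 0.15 and 1.0).
#' @param energy_offset constant added to every state's energy, kBT
#'   (default 0).  A pure gauge: the partition function cancels it, so all
#'   predicted distributions are invariant under it.
#' @param outer_turn_bp extent of the weakly bound outer region from each
#'   end, bp (default 39).
#' @param angle_bin device-angle bin width in degrees (default 5).
#' @param unwrap_bin unwrapped-bp bin width w (default 3).
#' @param backend `"planar"` (pitch ignored) or `"helix"` (3-D superhelix).
#' @return An object of class `nucleosome_spec`.
#' @export
nucleosome_spec <- function(total_bp = 249L, wrapped_bp = 147L,
                            linker_bp = 51L,
                            superhelix_radius = 4.18,
                            superhelix_turns = 1.67,
                            superhelix_pitch = 2.39,
                            rise_per_bp = 0.34,
                            gamma_outer = 0.15, gamma_inner = 1.0,
                            energy_offset = 0,
                            outer_turn_bp = 39L,
                            angle_bin = 5, unwrap_bin = 3L,
                            backend = c("planar", "helix")) {
  backend <- match.arg(backend)
  if (wrapped_bp + 2 * linker_bp > total_bp)
    stop("wrapped_bp + 2 * linker_bp must not exceed total_bp", call. = FALSE)
  for (nm in c("superhelix_radius", "superhelix_turns", "rise_per_bp",
               "angle_bin", "unwrap_bin"))
    stop_if_not_positive(get(nm), nm)
  structure(list(total_bp = total_bp, wrapped_bp = wrapped_bp,
                 linker_bp = linker_bp,
                 superhelix_radius = superhelix_radius,
                 superhelix_turns = superhelix_turns,
                 superhelix_pitch = superhelix_pitch,
                 rise_per_bp = rise_per_bp,
                 gamma_outer = gamma_outer, gamma_inner = gamma_inner,
                 energy_offset = energy_offset,
                 outer_turn_bp = outer_turn_bp,
                 angle_bin = angle_bin, unwrap_bin = unwrap_bin,
                 backend = backend),
            class = "nucleosome_spec")
}

#' @export
print.nucleosome_spec <- function(x, ...) {
  cat(sprintf("Nucleosome construct: %d bp total, %d wrapped, %d bp linkers (%s geometry)\n",
              x$total_bp, x$wrapped_bp, x$linker_bp, x$backend))
  cat(sprintf("  adhesion: %.2f kBT/bp outer (first %d bp), %.2f kBT/bp inner\n",
              x$gamma_outer, x$outer_turn_bp, x$gamma_inner))
  invisible(x)
}

check_unwrap_state <- function(n1, n2, spec) {
  if (any(n1 < 0 | n2 < 0 | n1 + n2 > spec$wrapped_bp))
    stop("unwrapping state requires n1, n2 >= 0 and n1 + n2 <= wrapped_bp",
         call. = FALSE)
}

#' Hinge angle implied by a nucleosome unwrapping state
#'
#' Builds the arm-tip span of the construct for unwrapping state `(n1, n2)`:
#' the remaining wrapped DNA follows the superhelical arc, the unwrapped
#' stretches (`n1`/`n2` bp plus the free linker on each side) leave along
#' straight lines tangent to the wrap at the last point of contact, and the
#' span between the two free ends is inverted through the chord relation
#' `span = 2 r sin(theta/2)` to a hinge angle.  With the `"planar"` backend
#' the superhelix is projected to a circle; `"helix"` keeps the 2.39-nm
#' pitch.  Because the wrap exceeds a full turn, the exit tangents rotate
#' through more than 360 degrees during unwrapping and the resulting angle
#' map is genuinely non-monotone over the first turn (a property of spool
#' geometry, not an artifact).
#'
#' @param n1,n2 bp unwrapped from each end (vectors recycled to common
#'   length).
#' @param spec a [nucleosome_spec()].
#' @param geometry a [hinge_geometry()].
#' @return Hinge angle(s) in degrees, clamped to \[0, 180\] (with a warning
#'   when the span exceeds the fully open chord).
#' @export
unwrap_geometry_angle <- function(n1, n2, spec = nucleosome_spec(),
                                  geometry = hinge_geometry()) {
  stopifnot(inherits(spec, "nucleosome_spec"),
            inherits(geometry, "hinge_geometry"))
  check_unwrap_state(n1, n2, spec)
  k <- cbind(n1, n2)                       # recycles
  span <- unwrap_span(k[, 1], k[, 2], spec)
  r2 <- 2 * geometry$attachment_radius
  if (any(span > r2))
    warning("required span exceeds the fully open device; angle clamped to 180 deg",
            call. = FALSE)
  unname(rad2deg(2 * asin(pmin(1, span / r2))))
}

## Arm-tip span (nm) of state (n1, n2); vectorized.
unwrap_span <- function(n1, n2, spec) {
  omega <- spec$superhelix_turns * 2 * pi / spec$wrapped_bp  # rad/bp
  half <- spec$wrapped_bp * omega / 2
  a1 <- -half + n1 * omega                 # exit on side 1 (bp index n1)
  a2 <- half - n2 * omega                  # exit on side 2
  t1 <- spec$rise_per_bp * (n1 + spec$linker_bp)
  t2 <- spec$rise_per_bp * (n2 + spec$linker_bp)
  rho <- spec$superhelix_radius
  if (spec$backend == "planar") {
    ## side 1 extends along the tangent in the decreasing-bp direction,
    ## side 2 in the increasing-bp direction
    e1x <- rho * cos(a1) + t1 * sin(a1)
    e1y <- rho * sin(a1) - t1 * cos(a1)
    e2x <- rho * cos(a2) - t2 * sin(a2)
    e2y <- rho * sin(a2) + t2 * cos(a2)
    sqrt((e1x - e2x)^2 + (e1y - e2y)^2)
  } else {
    zslope <- spec$superhelix_pitch / (2 * pi)   # dz per rad of wrap
    tn <- sqrt(rho^2 + zslope^2)                 # tangent norm per rad
    e1x <- rho * cos(a1) + t1 * sin(a1) * rho / tn
    e1y <- rho * sin(a1) - t1 * cos(a1) * rho / tn
    e1z <- zslope * a1 - t1 * zslope / tn
    e2x <- rho * cos(a2) - t2 * sin(a2) * rho / tn
    e2y <- rho * sin(a2) + t2 * cos(a2) * rho / tn
    e2z <- zslope * a2 + t2 * zslope / tn
    sqrt((e1x - e2x)^2 + (e1y - e2y)^2 + (e1z - e2z)^2)
  }
}

#' Unwrapping free energy of a state
#'
#' Piecewise-constant per-bp adhesion model: releasing bp `k` (counted from
#' an end) costs `gamma_outer` kBT for `k <= outer_turn_bp` and
#' `gamma_inner` kBT beyond, independently for the two ends, so the energy
#' is additive: `eps(n1, n2) = eps(n1, 0) + eps(0, n2)` with
#' `eps(0, 0) = 0` (when the gauge `energy_offset` is zero).
#'
#' @inheritParams unwrap_geometry_angle
#' @return Free energy in kBT.
#' @export
unwrap_energy <- function(n1, n2, spec = nucleosome_spec()) {
  stopifnot(inherits(spec, "nucleosome_spec"))
  check_unwrap_state(n1, n2, spec)
  end_cost <- function(n) {
    outer <- pmin(n, spec$outer_turn_bp)
    outer * spec$gamma_outer + (n - outer) * spec$gamma_inner
  }
  k <- cbind(n1, n2)
  unname(end_cost(k[, 1]) + end_cost(k[, 2])) + spec$energy_offset
}

## Enumerate all unwrapping states with their angle, energy and prior mass.
## P_theta is the device prior's probability mass at the bin containing the
## state's implied angle (zero outside the prior's support).
unwrap_state_table <- function(device_dist, spec, geometry,
                               flat_prior = FALSE) {
  wb <- spec$wrapped_bp
  n1 <- rep(0:wb, times = wb + 1L)
  n2 <- rep(0:wb, each = wb + 1L)
  keep <- n1 + n2 <= wb
  n1 <- n1[keep]; n2 <- n2[keep]
  theta <- suppressWarnings(unwrap_geometry_angle(n1, n2, spec, geometry))
  eps <- unwrap_energy(n1, n2, spec)
  if (flat_prior) {
    P <- rep(1, length(theta))
    bin <- rep(NA_integer_, length(theta))
  } else {
    stopifnot(inherits(device_dist, "angular_distribution"))
    bin <- findInterval(theta, device_dist$bin_edges,
                        rightmost.closed = TRUE)
    inside <- bin >= 1L & bin <= length(device_dist$density)
    P <- numeric(length(theta))
    P[inside] <- bin_mass(device_dist)[bin[inside]]
  }
  data.frame(n1 = n1, n2 = n2, theta = theta, eps = eps, P = P, bin = bin)
}

#' Predicted distribution of total unwrapped base pairs
#'
#' Exhaustive enumeration of all unwrapping states `(n1, n2)`.  Each state
#' carries the Boltzmann weight `P_theta(n1, n2) exp(-eps(n1, n2))` where
#' `P_theta` is the device prior's probability mass at the hinge-angle bin
#' implied by the state's geometry and `eps` is in kBT.  States are sorted
#' into bins of total unwrapped bp (width `w = unwrap_bin`), and the binned
#' weights are normalized by `w Z` with `Z` the sum over all states, giving
#' a probability density per bp.
#'
#' @param device_dist an `angular_distribution`: the free device's measured
#'   or synthetic angle distribution.  Ignored when `flat_prior = TRUE`
#'   (free nucleosome in solution: every angle equally likely, so the
#'   distribution reduces to the Boltzmann factor of `eps` alone).
#' @param spec a [nucleosome_spec()].
#' @param geometry a [hinge_geometry()].
#' @param flat_prior set `TRUE` for the free-nucleosome reference.
#' @return An object of class `unwrap_distribution` with `breaks` (bp bin
#'   edges), `mids`, `density` (per bp) and `bin_width`.
#' @export
predict_unwrap_distribution <- function(device_dist = NULL,
                                        spec = nucleosome_spec(),
                                        geometry = hinge_geometry(),
                                        flat_prior = is.null(device_dist)) {
  stopifnot(inherits(spec, "nucleosome_spec"))
  st <- unwrap_state_table(device_dist, spec, geometry, flat_prior)
  wgt <- st$P * exp(-st$eps)
  if (all(wgt == 0))
    stop("device prior assigns zero mass to every reachable angle",
         call. = FALSE)
  w <- spec$unwrap_bin
  total <- st$n1 + st$n2
  ibin <- total %/% w
  nb <- max(ibin) + 1L
  mass <- vapply(0:(nb - 1L), function(i) sum(wgt[ibin == i]), numeric(1))
  Z <- sum(wgt)
  structure(list(breaks = seq(0, nb * w, by = w),
                 mids = seq(0, nb - 1L) * w + (w - 1) / 2,
                 density = mass / (w * Z),
                 bin_width = w),
            class = "unwrap_distribution")
}

#' @export
print.unwrap_distribution <- function(x, ...) {
  cat(sprintf("Unwrapping distribution: %d bins of %g bp, mean total %.1f bp\n",
              length(x$density), x$bin_width, mean_unwrapped(x)))
  invisible(x)
}

#' Mean total unwrapped base pairs of an unwrapping distribution
#'
#' @param x an `unwrap_distribution`.
#' @return Mean of the binned total, in bp.
#' @export
mean_unwrapped <- function(x) {
  stopifnot(inherits(x, "unwrap_distribution"))
  sum(x$mids * x$density * x$bin_width)
}

#' Device angle distribution constrained by an incorporated nucleosome
#'
#' Marginalizes the joint state weight `P_theta exp(-eps) / Z` over the
#' unwrapping states mapping into each device-angle bin, yielding the
#' predicted angle distribution of the device with the nucleosome bound.
#' With a flat energy model (all `eps` equal) this reduces to the device
#' prior restricted to reachable angles, renormalized.
#'
#' @inheritParams predict_unwrap_distribution
#' @return An `angular_distribution` on the device prior's bins.
#' @export
predict_constrained_angle_distribution <- function(device_dist,
                                                   spec = nucleosome_spec(),
                                                   geometry = hinge_geometry()) {
  stopifnot(inherits(device_dist, "angular_distribution"),
            inherits(spec, "nucleosome_spec"))
  st <- unwrap_state_table(device_dist, spec, geometry, flat_prior = FALSE)
  wgt <- st$P * exp(-st$eps)
  if (all(wgt == 0))
    stop("device prior assigns zero mass to every reachable angle",
         call. = FALSE)
  mass <- numeric(length(device_dist$density))
  agg <- tapply(wgt, st$bin, sum)
  idx <- as.integer(names(agg))
  ok <- idx >= 1L & idx <= length(mass)
  mass[idx[ok]] <- agg[ok]
  widths <- diff(device_dist$bin_edges)
  angular_distribution(device_dist$bin_edges, mass / sum(mass) / widths)
}

#' Tensile force from a device landscape at a constrained angle
#'
#' Differentiates the free-device free-energy landscape at `theta_star`, the
#' most likely angle of the device with the sample incorporated, and
#' projects the angular slope onto the sample axis through the chord rule:
#' `F = -(dG/dtheta) / (dr/dtheta)` with
#' `dr/dtheta = r_att cos(theta/2)`.  When the free-device landscape slopes
#' downward toward larger angles at `theta_star` (the device "wants" to
#' open), the result is positive: tension on the sample holding it closed.
#' The alternative torque-over-radius estimate
#' `-(dG/dtheta) / r_att` is attached as attribute
#' `"torque_over_radius"`.
#'
#' @param landscape a [boltzmann_free_energy()] result for the free device.
#' @param theta_star constrained most-likely angle, degrees; must lie
#'   strictly inside the landscape's valid range.
#' @param geometry a [hinge_geometry()].
#' @param thermal a [thermal_scale()].
#' @param dtheta finite-difference half-step in degrees (default 0.1).
#' @return Force in pN (positive = tensile on the sample).
#' @export
tensile_force_estimate <- function(landscape, theta_star,
                                   geometry = hinge_geometry(),
                                   thermal = thermal_scale(),
                                   dtheta = 0.1) {
  stopifnot(inherits(landscape, "free_energy_landscape"),
            inherits(geometry, "hinge_geometry"))
  vr <- landscape$valid_range
  if (theta_star - dtheta < vr[1] || theta_star + dtheta > vr[2])
    stop("`theta_star` is at or beyond the landscape's valid range; derivative undefined",
         call. = FALSE)
  dGdth <- (landscape_G(landscape, theta_star + dtheta) -
            landscape_G(landscape, theta_star - dtheta)) /
           (2 * deg2rad(dtheta)) * thermal$kBT        # pN nm per rad
  drdth <- geometry$attachment_radius * cos(deg2rad(theta_star) / 2)
  structure(-dGdth / drdth,
            torque_over_radius = -dGdth / geometry$attachment_radius)
}
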