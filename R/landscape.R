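## Boltzmann inversion of hinge-angle ensembles: probability densities,
## free-energy landscapes, torque profiles, polar force maps, bootstrap
## uncertainties.

#' Hinge-angle ensemble
#'
#' Raw per-particle hinge angles for one device variant, the proxy for a set
#' of TEM angle measurements.  Angles are interior hinge angles in degrees,
#' strictly inside (0, 180).
#'
#' @param angles numeric vector of angles in degrees.
#' @param device_label text label of the device variant.
#' @param source `"measured"` or `"synthetic"`.
#' @return An object of class `angle_ensemble`.
#' @export
angle_ensemble <- function(angles, device_label = "device",
                           source = c("measured", "synthetic")) {
  source <- match.arg(source)
  if (length(angles) < 1L || !is.numeric(angles))
    stop("`angles` must contain at least one numeric value", call. = FALSE)
  if (any(!is.finite(angles) | angles <= 0 | angles >= 180))
    stop("all angles must lie strictly inside (0, 180) degrees",
         call. = FALSE)
  structure(list(angles = as.numeric(angles),
                 device_label = as.character(device_label),
                 source = source),
            class = "angle_ensemble")
}

#' @export
print.angle_ensemble <- function(x, ...) {
  cat(sprintf("Angle ensemble '%s' (%s): N = %d, mean %.1f deg, range [%.1f, %.1f]\n",
              x$device_label, x$source, length(x$angles), mean(x$angles),
              min(x$angles), max(x$angles)))
  invisible(x)
}

#' @export
length.angle_ensemble <- function(x) length(x$angles)

#' Histogram probability density of an angle ensemble
#'
#' Bins the ensemble on a grid whose bin *centers* sit at integer multiples
#' of `bin_width` (so with the 5-degree default the bins are
#' \[77.5, 82.5), \[82.5, 87.5), ...), and normalizes counts to a
#' probability density per degree.  Empty bins inside the occupied range are
#' kept; empty bins outside it are trimmed.
#'
#' @param ensemble an [angle_ensemble()].
#' @param bin_width bin width in degrees (default 5).
#' @return An object of class `angular_distribution` with fields
#'   `bin_edges` (length nbins + 1), `mids`, `density` (per degree),
#'   `bin_width`, and `n` (sample size; `NA` for model-derived
#'   distributions).
#' @export
estimate_density <- function(ensemble, bin_width = 5) {
  stopifnot(inherits(ensemble, "angle_ensemble"))
  stop_if_not_positive(bin_width, "bin_width")
  a <- ensemble$angles
  if (length(a) < 150L)
    warning(sprintf("sample size %d is below the ~150 needed for a converged landscape",
                    length(a)), call. = FALSE)
  lo <- floor(min(a) / bin_width + 0.5) - 0.5
  hi <- floor(max(a) / bin_width + 0.5) + 0.5
  edges <- seq(lo, hi, by = 1) * bin_width
  counts <- tabulate(findInterval(a, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)
  angular_distribution(edges, counts / (length(a) * bin_width), n = length(a))
}

#' Angular probability distribution on a bin grid
#'
#' Low-level constructor; most users obtain one from [estimate_density()] or
#' from the model predictors.  The density must integrate to 1 over degrees.
#'
#' @param bin_edges ascending bin edges in degrees.
#' @param density probability density per degree for each bin (length
#'   `length(bin_edges) - 1`).
#' @param n sample size behind the distribution, if any.
#' @return An object of class `angular_distribution`.
#' @export
angular_distribution <- function(bin_edges, density, n = NA_integer_) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("`bin_edges` must be strictly ascending", call. = FALSE)
  if (length(density) != length(bin_edges) - 1L)
    stop("`density` must have one value per bin", call. = FALSE)
  if (any(density < 0)) stop("`density` must be non-negative", call. = FALSE)
  w <- diff(bin_edges)
  total <- sum(density * w)
  if (abs(total - 1) > 1e-9)
    stop(sprintf("density integrates to %.12f, not 1", total), call. = FALSE)
  structure(list(bin_edges = as.numeric(bin_edges),
                 mids = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
                 density = as.numeric(density),
                 bin_width = if (length(unique(round(w, 9))) == 1L) w[1] else NA_real_,
                 n = n),
            class = "angular_distribution")
}

#' @export
print.angular_distribution <- function(x, ...) {
  cat(sprintf("Angular distribution: %d bins over [%.1f, %.1f] deg, peak at %.1f deg\n",
              length(x$density), min(x$bin_edges), max(x$bin_edges),
              x$mids[which.max(x$density)]))
  invisible(x)
}

#' @export
plot.angular_distribution <- function(x, ...,
                                      xlab = "hinge angle (deg)",
                                      ylab = "probability density (1/deg)") {
  graphics::plot(x$mids, x$density, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

## probability mass per bin
bin_mass <- function(dist) dist$density * diff(dist$bin_edges)

#' Most likely angle of a distribution
#'
#' Argmax of the spline-smoothed density (cubic smoothing spline through the
#' bin midpoints, smoothing chosen by generalized cross-validation unless
#' `spar` is given), evaluated on a 0.1-degree grid.
#'
#' @param dist an `angular_distribution`.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @return Peak angle in degrees.
#' @export
peak_angle <- function(dist, spar = NULL) {
  stopifnot(inherits(dist, "angular_distribution"))
  keep <- dist$density > 0
  if (sum(keep) < 4L) return(dist$mids[which.max(dist$density)])
  fit <- if (is.null(spar)) smooth.spline(dist$mids[keep], dist$density[keep])
         else smooth.spline(dist$mids[keep], dist$density[keep], spar = spar)
  g <- seq(min(dist$mids[keep]), max(dist$mids[keep]), by = 0.1)
  g[which.max(predict(fit, g)$y)]
}

#' Boltzmann-inversion free-energy landscape
#'
#' `G(theta) = -ln p(theta)` in kBT units, computed on the contiguous run of
#' bins around the density maximum where the density is at least `cutoff`
#' (default 0.001 per degree, the edge cutoff below which too few
#' conformations are observed).  The minimum over the retained range is
#' shifted to zero and a cubic smoothing spline is fit through the retained
#' points (generalized cross-validation by default).
#'
#' @param dist an `angular_distribution`.
#' @param cutoff density cutoff per degree (default 0.001).
#' @param spar optional smoothing parameter for [stats::smooth.spline()].
#' @return An object of class `free_energy_landscape` with fields `theta`
#'   (bin centers, degrees), `G` (kBT), `valid_range`, `spline` and
#'   `bin_width`.
#' @export
boltzmann_free_energy <- function(dist, cutoff = 0.001, spar = NULL) {
  stopifnot(inherits(dist, "angular_distribution"))
  ok <- dist$density >= cutoff & dist$density > 0
  if (!any(ok))
    stop("all bins fall below the density cutoff; cannot estimate a landscape",
         call. = FALSE)
  ## contiguous run containing the global density maximum
  imax <- which.max(dist$density)
  i0 <- imax; while (i0 > 1L && ok[i0 - 1L]) i0 <- i0 - 1L
  i1 <- imax; while (i1 < length(ok) && ok[i1 + 1L]) i1 <- i1 + 1L
  idx <- i0:i1
  theta <- dist$mids[idx]
  G <- -log(dist$density[idx])
  G <- G - min(G)
  spline <- if (length(idx) >= 4L) {
    if (is.null(spar)) smooth.spline(theta, G) else smooth.spline(theta, G, spar = spar)
  } else NULL
  structure(list(theta = theta, G = G,
                 valid_range = range(theta),
                 spline = spline,
                 bin_width = dist$bin_width),
            class = "free_energy_landscape")
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("Free-energy landscape: %d points over [%.1f, %.1f] deg, max G = %.2f kBT\n",
              length(x$theta), x$valid_range[1], x$valid_range[2], max(x$G)))
  invisible(x)
}

#' @export
plot.free_energy_landscape <- function(x, ...,
                                       xlab = "hinge angle (deg)",
                                       ylab = "G (kBT)") {
  graphics::plot(x$theta, x$G, xlab = xlab, ylab = ylab, ...)
  if (!is.null(x$spline)) {
    g <- seq(x$valid_range[1], x$valid_range[2], by = 0.1)
    graphics::lines(g, predict(x$spline, g)$y)
  }
  invisible(x)
}

## Evaluate the landscape's smoothed G (kBT) at angles (deg); falls back to
## linear interpolation when the landscape is too narrow for a spline.
landscape_G <- function(landscape, theta) {
  if (!is.null(landscape$spline)) predict(landscape$spline, theta)$y
  else approx(landscape$theta, landscape$G, xout = theta, rule = 2)$y
}

#' Torque profile of a device from its free-energy landscape
#'
#' Differentiates the smoothed landscape: `torque(theta) = -dG/dtheta` with
#' the derivative taken in radians and scaled by kBT, giving pN nm.  The
#' derivative is a centered finite difference of spline evaluations on a
#' fine grid (default 0.1 degrees).  Positive torque acts to open the hinge.
#'
#' @param landscape a [boltzmann_free_energy()] result with at least 3 valid
#'   points.
#' @param thermal a [thermal_scale()].
#' @param dtheta evaluation grid spacing in degrees.
#' @return An object of class `torque_force_profile` with fields `theta`
#'   (degrees), `torque` (pN nm) and the generating landscape.
#' @export
torque_profile <- function(landscape, thermal = thermal_scale(),
                           dtheta = 0.1) {
  stopifnot(inherits(landscape, "free_energy_landscape"),
            inherits(thermal, "thermal_scale"))
  if (length(landscape$theta) < 3L)
    stop("landscape narrower than 3 bins; torque undefined", call. = FALSE)
  g <- seq(landscape$valid_range[1], landscape$valid_range[2], by = dtheta)
  Gk <- landscape_G(landscape, g)          # kBT
  h <- deg2rad(dtheta)
  dG <- numeric(length(g))
  dG[2:(length(g) - 1)] <- (Gk[-(1:2)] - Gk[1:(length(g) - 2)]) / (2 * h)
  dG[1] <- (Gk[2] - Gk[1]) / h
  dG[length(g)] <- (Gk[length(g)] - Gk[length(g) - 1]) / h
  structure(list(theta = g,
                 torque = -dG * thermal$kBT,
                 landscape = landscape,
                 kBT = thermal$kBT),
            class = "torque_force_profile")
}

#' @export
print.torque_force_profile <- function(x, ...) {
  cat(sprintf("Torque profile: [%.1f, %.1f] deg, torque range [%.2f, %.2f] pN nm\n",
              min(x$theta), max(x$theta), min(x$torque), max(x$torque)))
  invisible(x)
}

#' Polar force map over angle and radial position
#'
#' `F(theta, d) = torque(theta) / d` for radial positions `d` along the
#' hinge arms.  The default radial range starts at 11 nm, the typical 32-bp
#' crossover repeat of a square-lattice origami bundle, and ends at the
#' 61-nm arm tip.  Sign follows the torque: positive force is tensile on a
#' sample spanning the arms, negative compressive.
#'
#' @param profile a [torque_profile()] result.
#' @param d_min,d_max radial range in nm (defaults 11 and 61).
#' @param n_d number of radial grid points.
#' @return A list of class `force_map` with `theta` (deg), `d` (nm) and the
#'   `force` matrix (pN, angles in rows).
#' @export
force_map <- function(profile, d_min = 11, d_max = 61, n_d = 51L) {
  stopifnot(inherits(profile, "torque_force_profile"))
  stop_if_not_positive(d_min, "d_min")
  if (d_max <= d_min) stop("`d_max` must exceed `d_min`", call. = FALSE)
  d <- seq(d_min, d_max, length.out = n_d)
  structure(list(theta = profile$theta, d = d,
                 force = outer(profile$torque, d, `/`)),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("Force map: %d angles x %d radii, force range [%.2f, %.2f] pN\n",
              length(x$theta), length(x$d), min(x$force), max(x$force)))
  invisible(x)
}

#' Bootstrap uncertainty of an ensemble-derived statistic
#'
#' Resamples the ensemble with replacement (N from N), recomputes the
#' statistic for each replicate, and returns the replicate mean and standard
#' deviation.  The statistic may return a vector (e.g. a landscape on a
#' fixed grid); replicates on which it fails (for instance an empty valid
#' range) are skipped and counted, and more than 50% skips is an error.
#'
#' @param ensemble an [angle_ensemble()].
#' @param statistic function taking a numeric vector of angles and returning
#'   a numeric scalar or fixed-length vector.
#' @param replicates number of bootstrap replicates (default 50).
#' @param seed integer seed for reproducibility.
#' @return An object of class `bootstrap_result` with `point_estimate`
#'   (statistic on the full ensemble), `mean`, `sd`, `replicates` (used) and
#'   `skipped`.
#' @export
bootstrap_uncertainty <- function(ensemble, statistic, replicates = 50L,
                                  seed = 1L) {
  stopifnot(inherits(ensemble, "angle_ensemble"), is.function(statistic))
  if (replicates < 2L) stop("`replicates` must be at least 2", call. = FALSE)
  a <- ensemble$angles
  point <- statistic(a)
  set.seed(seed)
  reps <- vector("list", replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    res <- tryCatch(statistic(sample(a, length(a), replace = TRUE)),
                    error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res))) skipped <- skipped + 1L
    else reps[[r]] <- res
  }
  if (skipped > replicates / 2)
    stop(sprintf("statistic failed on %d of %d bootstrap replicates",
                 skipped, replicates), call. = FALSE)
  m <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  structure(list(point_estimate = point,
                 mean = colMeans(m),
                 sd = apply(m, 2, sd),
                 replicates = nrow(m),
                 skipped = skipped),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates (%d skipped)\n", x$replicates, x$skipped))
  if (length(x$point_estimate) == 1L)
    cat(sprintf("  estimate %.4g +/- %.4g (SD)\n", x$point_estimate, x$sd))
  invisible(x)
}
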