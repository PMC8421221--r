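## Synthetic-data generators: device-variant angle ensembles emulating TEM
## measurements, WLC end-to-end samples, and a Monte-Carlo oracle for the
## coupling model.  All generators are pure functions of (parameters, seed).

#' Device-variant angle model
#'
#' Truncated skew-normal emulation of a device variant's hinge-angle
#' distribution, with additive measurement noise standing in for the manual
#' two-line angle measurement on micrographs.  The named variants are
#' calibrated once to the reported summary statistics:
#'
#' * `nDFS.A` -- mean 70 deg, flexible over ~50--100 deg with tails to
#'   25/125 deg (location 70, scale 14, no skew, N = 700).
#' * `nDFS.B` -- mean 83 deg, bulk 70--110 deg, ~90% of mass above 60 deg
#'   (location 83, scale 12, no skew, N = 500).
#' * `nDFS.C-35` -- closed variant, ~93% of mass below 60 deg, primarily
#'   10--50 deg (location 25, scale 19, right skew 4, N = 500).
#'
#' @param label variant name, or `"custom"` with explicit parameters.
#' @param location,scale,skew skew-normal location (deg), scale (deg) and
#'   shape; overridden defaults for the named variants.
#' @param noise_sd measurement-noise SD in degrees (default 2).
#' @param default_N default ensemble size.
#' @return An object of class `device_variant`.
#' @export
device_variant <- function(label = c("nDFS.A", "nDFS.B", "nDFS.C-35",
                                     "custom"),
                           location = NULL, scale = NULL, skew = NULL,
                           noise_sd = 2, default_N = NULL) {
  label <- match.arg(label)
  defaults <- switch(label,
    "nDFS.A"    = list(location = 70, scale = 14, skew = 0, default_N = 700L),
    "nDFS.B"    = list(location = 83, scale = 12, skew = 0, default_N = 500L),
    "nDFS.C-35" = list(location = 25, scale = 19, skew = 4, default_N = 500L),
    "custom"    = list(location = location, scale = scale, skew = skew %||% 0,
                       default_N = default_N %||% 500L))
  location <- location %||% defaults$location
  scale <- scale %||% defaults$scale
  skew <- skew %||% defaults$skew
  default_N <- default_N %||% defaults$default_N
  if (is.null(location) || is.null(scale))
    stop("custom variants need `location` and `scale`", call. = FALSE)
  stop_if_not_positive(scale, "scale")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(label = label, location = location, scale = scale,
                 skew = skew, noise_sd = noise_sd, default_N = default_N),
            class = "device_variant")
}

#' @export
print.device_variant <- function(x, ...) {
  cat(sprintf("Device variant %s: skew-normal(location %g, scale %g, shape %g) + %g deg noise\n",
              x$label, x$location, x$scale, x$skew, x$noise_sd))
  invisible(x)
}

## Skew-normal draws via the delta representation: with (u0, u1) iid N(0,1),
## z = delta |u0| + sqrt(1 - delta^2) u1 is skew-normal(shape alpha),
## delta = alpha / sqrt(1 + alpha^2).
rskewnorm <- function(n, location, scale, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n); u1 <- rnorm(n)
  location + scale * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}

## Skew-normal density, for distributional checks on the sampler.
dskewnorm <- function(x, location, scale, alpha) {
  z <- (x - location) / scale
  2 / scale * stats::dnorm(z) * stats::pnorm(alpha * z)
}

#' Generate a synthetic hinge-angle ensemble
#'
#' Draws `N` angles from the variant's truncated skew-normal, adds
#' independent Gaussian measurement noise, and rejects any draw outside
#' (0, 180) degrees.  Identical seeds give identical ensembles.
#'
#' @param model a [device_variant()].
#' @param N ensemble size (default: the variant's `default_N`).
#' @param seed integer seed.
#' @return An [angle_ensemble()] with `source = "synthetic"`.
#' @export
generate_angle_ensemble <- function(model, N = model$default_N, seed = 1L) {
  stopifnot(inherits(model, "device_variant"))
  if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < N) {
    draw <- rskewnorm(2L * (N - length(out)) + 16L,
                      model$location, model$scale, model$skew) +
            rnorm(2L * (N - length(out)) + 16L, 0, model$noise_sd)
    out <- c(out, draw[draw > 0 & draw < 180])
  }
  angle_ensemble(out[seq_len(N)], device_label = model$label,
                 source = "synthetic")
}

#' Sample WLC end-to-end distances by inverse-CDF
#'
#' Draws scalar end-to-end distances from the normalized stiff-polymer
#' density via inverse transform sampling on a fine grid (trapezoidal CDF,
#' linear interpolation).  Serves as the distributional oracle for
#' [wlc_frey_pdf()] and as a stand-in for measured dsDNA EEDs.
#'
#' @param spec a [wlc()].
#' @param N sample count.
#' @param seed integer seed.
#' @param grid_n CDF grid resolution (default 4001).
#' @return Numeric vector of distances in nm, all inside (0, Lc).
#' @export
sample_wlc_eed <- function(spec, N, seed = 1L, grid_n = 4001L) {
  stopifnot(inherits(spec, "wlc"))
  if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
  g <- seq(0, spec$Lc, length.out = grid_n)
  p <- wlc_frey_pdf(g, spec)
  cdf <- c(0, cumsum((p[-1] + p[-grid_n]) / 2 * diff(g)))
  cdf <- cdf / cdf[grid_n]
  set.seed(seed)
  u <- runif(N)
  approx(cdf, g, xout = u, ties = "ordered")$y
}

#' Monte-Carlo oracle for the coupled angle distribution
#'
#' Importance-weighted Monte Carlo over the same model as
#' [predict_coupled_angle_distribution()]: hinge angles are drawn from the
#' prior (uniform within bins), the two linker end-to-end vectors from the
#' 3-D Gaussian (rejecting draws beyond the model's `n b` radial support),
#' and each draw is weighted by the sample density at the closure-implied
#' end-to-end distance.  The weighted angles are histogrammed on the
#' prior's bins.
#'
#' @param spec a [coupled_system()].
#' @param N Monte-Carlo sample count.
#' @param seed integer seed.
#' @return An `angular_distribution` on the prior's bins.
#' @export
sample_coupled_mc <- function(spec, N, seed = 1L) {
  stopifnot(inherits(spec, "coupled_system"))
  if (N < 1L) stop("`N` must be at least 1", call. = FALSE)
  set.seed(seed)
  prior <- spec$hinge_dist
  pm <- bin_mass(prior)
  bin <- sample.int(length(pm), N, replace = TRUE, prob = pm)
  theta <- runif(N, prior$bin_edges[bin], prior$bin_edges[bin + 1L])
  draw_linker <- function(chain) {
    sdc <- sqrt(chain$n * chain$b^2 / 3)
    v <- matrix(rnorm(3L * N, 0, sdc), ncol = 3L)
    r <- sqrt(rowSums(v^2))
    v[r >= chain$n * chain$b, ] <- NA_real_   # outside the model's support
    v
  }
  S <- draw_linker(spec$linker1) + draw_linker(spec$linker2)
  d <- chord_distance(theta, spec$geometry)
  RD <- sqrt(S[, 1]^2 + S[, 2]^2 + (d - S[, 3])^2)
  w <- ifelse(is.na(RD), 0, wlc_frey_pdf(ifelse(is.na(RD), 0, RD), spec$sample))
  if (sum(w) == 0)
    stop("all Monte-Carlo weights are zero: closure impossible everywhere",
         call. = FALSE)
  ess <- sum(w)^2 / sum(w^2)
  if (ess < 100)
    warning(sprintf("effective sample size %.1f < 100; increase N", ess),
            call. = FALSE)
  mass <- vapply(seq_along(pm),
                 function(k) sum(w[bin == k]), numeric(1)) / sum(w)
  angular_distribution(prior$bin_edges, mass / diff(prior$bin_edges),
                       n = N)
}

#' Write a reproducible fixture suite to disk
#'
#' Generates CSV angle tables for the three named device variants (N = 500
#' each), the 5-angle hand-checkable worked-example table, a WLC end-to-end
#' sample, and a JSON manifest recording every seed and parameter so the
#' suite can be regenerated byte-identically.
#'
#' @param dir output directory (created if needed).
#' @param seed integer master seed; per-file seeds are derived as
#'   `seed + 1, seed + 2, ...` and recorded in the manifest.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create fixture directory ", dir, call. = FALSE)
  variants <- c("nDFS.A", "nDFS.B", "nDFS.C-35")
  files <- list()
  rows <- list()
  for (i in seq_along(variants)) {
    ens <- generate_angle_ensemble(device_variant(variants[i]), N = 500L,
                                   seed = seed + i)
    rows[[i]] <- data.frame(angle_deg = round(ens$angles, 4),
                            device_label = variants[i])
  }
  angle_path <- file.path(dir, "device_angles.csv")
  write.csv(do.call(rbind, rows), angle_path, row.names = FALSE)
  files$device_angles <- "device_angles.csv"
  worked <- data.frame(angle_deg = c(80, 80, 80, 80, 90),
                       device_label = "worked-example")
  worked_path <- file.path(dir, "worked_example_angles.csv")
  write.csv(worked, worked_path, row.names = FALSE)
  files$worked_example <- "worked_example_angles.csv"
  eed <- sample_wlc_eed(wlc(85, 50), N = 1000L, seed = seed + 10L)
  eed_path <- file.path(dir, "wlc_eed_nm.csv")
  write.csv(data.frame(eed_nm = round(eed, 4)), eed_path, row.names = FALSE)
  files$wlc_eed <- "wlc_eed_nm.csv"
  manifest <- list(
    schema_version = 1L,
    master_seed = seed,
    files = files,
    device_variants = lapply(seq_along(variants), function(i) {
      m <- device_variant(variants[i])
      list(label = m$label, location = m$location, scale = m$scale,
           skew = m$skew, noise_sd = m$noise_sd, N = 500L, seed = seed + i)
    }),
    wlc = list(Lc = 85, lp = 50, N = 1000L, seed = seed + 10L))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
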