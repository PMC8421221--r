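test_that("histogram density uses bin centers at multiples of the width and normalizes per degree", {
  e1 <- suppressWarnings(estimate_density(angle_ensemble(rep(85, 100)), 5))
  expect_equal(sum(e1$density > 0), 1)
  expect_equal(max(e1$density), 0.2)
  e2 <- suppressWarnings(estimate_density(
    angle_ensemble(c(80, 80, 80, 80, 90)), 5))
  expect_equal(e2$bin_edges[1], 77.5)
  expect_equal(e2$density[e2$mids == 80], 0.16)
  expect_equal(e2$density[e2$mids == 90], 0.04)
  ## unit integral for an arbitrary synthetic ensemble
  ens <- generate_angle_ensemble(device_variant("nDFS.A"), 400, seed = 11)
  d <- estimate_density(ens, 5)
  expect_equal(sum(d$density * diff(d$bin_edges)), 1, tolerance = 1e-12)
  expect_error(angle_ensemble(numeric(0)), "at least one")
  expect_error(angle_ensemble(c(30, 190)), "inside")
})

test_that("Boltzmann inversion gives -ln p shifted to zero and honors the density cutoff", {
  fel_flat <- boltzmann_free_energy(flat_prior(50, 100))
  expect_true(all(abs(fel_flat$G) < 1e-12))
  ## two equal-width bins with densities 4:1 -> dG = ln 4
  d <- angular_distribution(c(75, 80, 85), c(0.16, 0.04))
  fel <- boltzmann_free_energy(d, cutoff = 0.001)
  expect_equal(diff(range(fel$G)), log(4))
  expect_equal(min(fel$G), 0)
  ## bins below the 0.001 cutoff at the edges are excluded
  dens <- c(0.0005, 0.055, 0.093, 0.05, 0.0005, 0.001)
  d2 <- angular_distribution(seq(50, 80, by = 5), dens)
  fel2 <- boltzmann_free_energy(d2, cutoff = 0.001)
  expect_equal(fel2$valid_range, c(57.5, 67.5))
  expect_equal(length(fel2$theta), 3)
  expect_error(boltzmann_free_energy(d2, cutoff = 1), "cutoff")
})

test_that("torque is the angular derivative of the landscape in pN nm", {
  th <- thermal_scale(kBT_ref)
  fel <- quadratic_landscape(k = 10, theta0 = 85)
  tq <- torque_profile(fel, th)
  ## analytic: torque = -k (theta - theta0) kBT, linear, zero at theta0
  expected <- -10 * (tq$theta - 85) * pi / 180 * kBT_ref
  inner <- seq(10, length(tq$theta) - 10)
  expect_equal(tq$torque[inner], expected[inner], tolerance = 1e-4)
  expect_equal(tq$torque[which.min(abs(tq$theta - 85))], 0,
               tolerance = 1e-6)
  ## a slope of 1 kBT/rad converts to 4.114 pN nm of torque
  lin <- structure(list(theta = seq(60, 80, 0.1),
                        G = (seq(60, 80, 0.1) - 60) * pi / 180,
                        valid_range = c(60, 80), spline = NULL,
                        bin_width = 0.1),
                   class = "free_energy_landscape")
  tql <- torque_profile(lin, th)
  expect_equal(median(abs(tql$torque)), kBT_ref, tolerance = 1e-6)
  ## above the single-well minimum the torque closes the hinge
  expect_true(all(tq$torque[tq$theta > 86] < 0))
  narrow <- structure(list(theta = c(80, 85), G = c(0, 1),
                           valid_range = c(80, 85), spline = NULL,
                           bin_width = 5),
                      class = "free_energy_landscape")
  expect_error(torque_profile(narrow, th), "3 bins")
})

test_that("force map divides torque by radius over the 11-61 nm arm range", {
  th <- thermal_scale(kBT_ref)
  tq <- torque_profile(quadratic_landscape(), th)
  fm <- force_map(tq)
  expect_equal(range(fm$d), c(11, 61))
  i <- which.min(abs(tq$torque - 4.114))
  expect_equal(fm$force[i, 1], tq$torque[i] / 11, tolerance = 1e-12)
  expect_equal(abs(tq$torque[i] / 11), 0.374, tolerance = 1e-2)
  ## inverse-radius scaling
  fm2 <- force_map(tq, d_min = 11, d_max = 44, n_d = 4L)  # d = 11,22,33,44
  expect_equal(fm2$force[, 2], fm2$force[, 1] / 2, tolerance = 1e-12)
  expect_error(force_map(tq, d_min = 0), "positive")
})

test_that("device-like synthetic landscapes produce forces within the reported order of magnitude", {
  ## the devices span roughly -3 pN (compression) to +5 pN (tension)
  th <- thermal_scale(kBT_ref)
  for (lbl in c("nDFS.A", "nDFS.B", "nDFS.C-35")) {
    ens <- generate_angle_ensemble(device_variant(lbl), 500, seed = 23)
    fel <- boltzmann_free_energy(estimate_density(ens, 5))
    fm <- force_map(torque_profile(fel, th))
    expect_gt(min(fm$force), -30)
    expect_lt(max(fm$force), 50)
    expect_lt(min(fm$force), -0.3)
    expect_gt(max(fm$force), 0.5)
  }
})

test_that("bootstrap resampling reproduces the CLT scale and is seed-stable", {
  const <- suppressWarnings(angle_ensemble(rep(85, 60)))
  b0 <- bootstrap_uncertainty(const, mean, replicates = 50, seed = 4)
  expect_equal(b0$sd, 0)
  expect_equal(b0$replicates, 50)
  set.seed(99)
  gauss <- angle_ensemble(pmin(179, pmax(1, rnorm(400, 85, 10))))
  b1 <- bootstrap_uncertainty(gauss, mean, replicates = 200, seed = 5)
  expect_equal(unname(b1$sd), 10 / sqrt(400), tolerance = 0.3)
  b2 <- bootstrap_uncertainty(gauss, mean, replicates = 200, seed = 5)
  expect_identical(b1$mean, b2$mean)
  ## statistics failing on more than half the replicates abort; resamples
  ## almost surely contain ties while the continuous original does not
  expect_error(
    bootstrap_uncertainty(gauss, function(a) {
      if (anyDuplicated(a)) stop("degenerate resample") else mean(a)
    }, replicates = 10, seed = 1),
    "failed")
  expect_error(bootstrap_uncertainty(gauss, mean, replicates = 1), "at least 2")
})

test_that("a synthetic ensemble recovers its generating landscape within 2 bootstrap SDs", {
  model <- device_variant("nDFS.B")
  truth_ens <- generate_angle_ensemble(model, 2e5, seed = 301)
  truth <- boltzmann_free_energy(estimate_density(truth_ens, 5))
  ens <- generate_angle_ensemble(model, 500, seed = 302)
  fel <- boltzmann_free_energy(estimate_density(ens, 5))
  shared <- intersect(fel$theta, truth$theta)
  interior <- shared[shared > min(shared) & shared < max(shared)]
  G_at <- function(a, at) {
    f <- boltzmann_free_energy(estimate_density(
      angle_ensemble(a, source = "synthetic"), 5))
    out <- approx(f$theta, f$G, xout = at)$y
    if (any(!is.finite(out))) stop("outside valid range")
    out
  }
  boot <- bootstrap_uncertainty(ens, function(a) G_at(a, interior),
                                replicates = 50, seed = 303)
  est <- approx(fel$theta, fel$G, xout = interior)$y
  tru <- approx(truth$theta, truth$G, xout = interior)$y
  expect_true(all(abs(est - tru) <= 2 * boot$sd + 1e-9))
})

test_that("two independent N = 150 ensembles agree to 0.5 kBT RMS over the shared range", {
  model <- device_variant("nDFS.B")
  f1 <- boltzmann_free_energy(estimate_density(
    generate_angle_ensemble(model, 150, seed = 401), 5))
  f2 <- boltzmann_free_energy(estimate_density(
    generate_angle_ensemble(model, 150, seed = 402), 5))
  shared <- intersect(f1$theta, f2$theta)
  g1 <- approx(f1$theta, f1$G, xout = shared)$y
  g2 <- approx(f2$theta, f2$G, xout = shared)$y
  expect_lt(sqrt(mean((g1 - g2)^2)), 0.5)
})

test_that("integrating the torque back recovers the free-energy landscape", {
  ens <- generate_angle_ensemble(device_variant("nDFS.B"), 500, seed = 7)
  fel <- boltzmann_free_energy(estimate_density(ens, 5))
  tq <- torque_profile(fel, thermal_scale(kBT_ref))
  th_rad <- tq$theta * pi / 180
  Gint <- pracma::cumtrapz(th_rad, -tq$torque / kBT_ref)[, 1]
  Gref <- predict(fel$spline, tq$theta)$y
  Gint <- Gint - Gint[1] + Gref[1]
  expect_lt(sqrt(mean((Gint - Gref)^2)), 0.02 * max(Gref))
})
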