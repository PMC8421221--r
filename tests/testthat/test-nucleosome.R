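geo <- hinge_geometry(61)

test_that("unwrapping geometry is symmetric and monotone for a sub-turn construct", {
  s <- sapply(0:30, function(n) unwrap_geometry_angle(n, 0, toy_spec, geo))
  expect_true(all(diff(s) > 0))
  expect_equal(unwrap_geometry_angle(7, 21, toy_spec, geo),
               unwrap_geometry_angle(21, 7, toy_spec, geo))
  full <- nucleosome_spec()
  expect_equal(unwrap_geometry_angle(12, 40, full, geo),
               unwrap_geometry_angle(40, 12, full, geo))
  expect_error(unwrap_geometry_angle(100, 100, full, geo), "wrapped_bp")
})

test_that("closed-form geometry matches a brute-force 3-D superhelix construction", {
  spec <- nucleosome_spec(backend = "helix")
  omega <- spec$superhelix_turns * 2 * pi / spec$wrapped_bp
  half <- spec$wrapped_bp * omega / 2
  rho <- spec$superhelix_radius
  helix_pt <- function(k) {
    a <- -half + k * omega
    c(rho * cos(a), rho * sin(a), spec$superhelix_pitch * a / (2 * pi))
  }
  brute_theta <- function(n1, n2) {
    dk <- 1e-5
    t1hat <- (helix_pt(n1 + dk) - helix_pt(n1 - dk))
    t1hat <- t1hat / sqrt(sum(t1hat^2))
    k2 <- spec$wrapped_bp - n2
    t2hat <- (helix_pt(k2 + dk) - helix_pt(k2 - dk))
    t2hat <- t2hat / sqrt(sum(t2hat^2))
    e1 <- helix_pt(n1) - spec$rise_per_bp * (n1 + spec$linker_bp) * t1hat
    e2 <- helix_pt(k2) + spec$rise_per_bp * (n2 + spec$linker_bp) * t2hat
    span <- sqrt(sum((e1 - e2)^2))
    2 * asin(min(1, span / (2 * geo$attachment_radius))) * 180 / pi
  }
  for (st in list(c(0, 0), c(10, 0), c(25, 40), c(70, 70)))
    expect_equal(unwrap_geometry_angle(st[1], st[2], spec, geo),
                 brute_theta(st[1], st[2]), tolerance = 1 / 10)
  ## the planar projection sits within a few degrees of the full helix at
  ## the fully wrapped baseline (the pitch adds ~7 nm of axial offset)
  expect_equal(unwrap_geometry_angle(0, 0, nucleosome_spec(), geo),
               unwrap_geometry_angle(0, 0, spec, geo), tolerance = 0.3)
})

test_that("the adhesion energy model is additive with a zero reference state", {
  spec <- nucleosome_spec()
  expect_equal(unwrap_energy(0, 0, spec), 0)
  for (st in list(c(5, 12), c(39, 2), c(60, 50)))
    expect_equal(unwrap_energy(st[1], st[2], spec),
                 unwrap_energy(st[1], 0, spec) + unwrap_energy(0, st[2], spec))
  ## outer-turn cost is per-bp gamma_outer, inner turn gamma_inner
  expect_equal(unwrap_energy(10, 0, spec), 10 * 0.15)
  expect_equal(unwrap_energy(45, 0, spec), 39 * 0.15 + 6 * 1.0)
})

test_that("thermal fluctuations alone unwrap the free nucleosome", {
  free <- predict_unwrap_distribution(flat_prior = TRUE)
  expect_gt(mean_unwrapped(free), 2)
  expect_lt(mean_unwrapped(free), 40)
  expect_gt(sum(free$density[free$mids > 3] * free$bin_width), 0.2)
})

test_that("with a flat device prior the distribution reduces to the Boltzmann state sum", {
  ## independent brute-force oracle: explicit double loop over (n1, n2)
  w <- toy_spec$unwrap_bin
  num <- numeric(0)
  for (n1 in 0:toy_spec$wrapped_bp) for (n2 in 0:(toy_spec$wrapped_bp - n1)) {
    i <- (n1 + n2) %/% w + 1L
    if (length(num) < i) num[i] <- 0
    num[i] <- num[i] + exp(-unwrap_energy(n1, n2, toy_spec))
  }
  oracle <- num / (w * sum(num))
  pred <- predict_unwrap_distribution(spec = toy_spec, geometry = geo,
                                      flat_prior = TRUE)
  expect_equal(pred$density, oracle, tolerance = 1e-14)
  expect_equal(sum(pred$density * pred$bin_width), 1, tolerance = 1e-12)
})

test_that("the exhaustive enumeration matches a naive oracle for a binned prior", {
  prior <- flat_prior(10, 120)
  ## perturb the prior so the angle weighting is non-trivial
  dens <- prior$density * seq(0.2, 2, length.out = length(prior$density))
  dens <- dens / sum(dens * diff(prior$bin_edges))
  prior <- angular_distribution(prior$bin_edges, dens)
  w <- toy_spec$unwrap_bin
  num <- numeric(0); Z <- 0
  for (n1 in 0:toy_spec$wrapped_bp) for (n2 in 0:(toy_spec$wrapped_bp - n1)) {
    th <- unwrap_geometry_angle(n1, n2, toy_spec, geo)
    b <- findInterval(th, prior$bin_edges, rightmost.closed = TRUE)
    P <- if (b >= 1 && b <= length(prior$density))
      prior$density[b] * diff(prior$bin_edges)[b] else 0
    wt <- P * exp(-unwrap_energy(n1, n2, toy_spec))
    i <- (n1 + n2) %/% w + 1L
    if (length(num) < i) num[i] <- 0
    num[i] <- num[i] + wt; Z <- Z + wt
  }
  pred <- predict_unwrap_distribution(prior, toy_spec, geo)
  expect_equal(pred$density, num / (w * Z), tolerance = 1e-14)
})

test_that("adding a constant to every state energy leaves all predictions unchanged", {
  prior <- estimate_density(
    generate_angle_ensemble(device_variant("nDFS.B"), 500, seed = 7), 5)
  base <- nucleosome_spec()
  lifted <- nucleosome_spec(energy_offset = 5)
  expect_equal(predict_unwrap_distribution(prior, base, geo)$density,
               predict_unwrap_distribution(prior, lifted, geo)$density,
               tolerance = 1e-12)
  expect_equal(predict_constrained_angle_distribution(prior, base, geo)$density,
               predict_constrained_angle_distribution(prior, lifted, geo)$density,
               tolerance = 1e-12)
})

test_that("open-biased device priors induce more unwrapping than closed-biased ones", {
  priorB <- estimate_density(
    generate_angle_ensemble(device_variant("nDFS.B"), 500, seed = 7), 5)
  priorC <- estimate_density(
    generate_angle_ensemble(device_variant("nDFS.C-35"), 500, seed = 8), 5)
  spec <- nucleosome_spec()
  mB <- mean_unwrapped(predict_unwrap_distribution(priorB, spec, geo))
  mC <- mean_unwrapped(predict_unwrap_distribution(priorC, spec, geo))
  free <- mean_unwrapped(predict_unwrap_distribution(flat_prior = TRUE))
  expect_gt(mB, mC)
  expect_gt(mC, free)
})

test_that("the constrained angle distribution marginalizes Eq-style weights correctly", {
  prior <- flat_prior(10, 120)
  ## flat energies: the constrained distribution is the prior's mass times
  ## the per-bin state multiplicity, renormalized
  flat_en <- nucleosome_spec(total_bp = 50L, wrapped_bp = 30L,
                             linker_bp = 10L, superhelix_turns = 0.45,
                             gamma_outer = 0, gamma_inner = 0)
  got <- predict_constrained_angle_distribution(prior, flat_en, geo)
  mult <- numeric(length(prior$density))
  for (n1 in 0:30) for (n2 in 0:(30 - n1)) {
    th <- unwrap_geometry_angle(n1, n2, flat_en, geo)
    b <- findInterval(th, prior$bin_edges, rightmost.closed = TRUE)
    if (b >= 1 && b <= length(mult)) mult[b] <- mult[b] + 1
  }
  want <- prior$density * mult
  want <- want / sum(want * diff(prior$bin_edges))
  expect_equal(got$density, want, tolerance = 1e-12)
  expect_equal(sum(got$density * diff(got$bin_edges)), 1, tolerance = 1e-12)
})

test_that("an incorporated nucleosome pulls the device peak to smaller angles", {
  priorB <- estimate_density(
    generate_angle_ensemble(device_variant("nDFS.B"), 500, seed = 7), 5)
  constrained <- predict_constrained_angle_distribution(priorB,
                                                        nucleosome_spec(),
                                                        geo)
  expect_lt(peak_angle(constrained), peak_angle(priorB))
})

test_that("tensile force estimates from the landscape follow the chord-projected derivative", {
  th <- thermal_scale(kBT_ref)
  flat <- quadratic_landscape(k = 0, theta0 = 85)
  expect_equal(as.numeric(tensile_force_estimate(flat, 80, geo, th)), 0,
               tolerance = 1e-12)
  fel <- quadratic_landscape(k = 10, theta0 = 85)
  for (ts in c(65, 70, 75)) {
    got <- tensile_force_estimate(fel, ts, geo, th)
    want <- kBT_ref * 10 * (85 - ts) * pi / 180 /
      (61 * cos(ts * pi / 360))
    expect_equal(as.numeric(got), want, tolerance = 0.01)
    expect_gt(as.numeric(got), 0)        # tension on the sample
  }
  expect_error(tensile_force_estimate(fel, 55, geo, th), "valid range")
})
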