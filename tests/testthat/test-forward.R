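test_that("central chords of a uniform disc match 2*R*mu", {
  n <- 128; pitch <- 5.4; R <- 32 * pitch; mu0 <- 50
  disc <- disc_map(n, pitch, R, mu0)
  sino <- ray_transform(disc, c(0, pi / 2), pitch)
  expect_equal(sino[1, n / 2], 2 * R * 1e-6 * mu0, tolerance = 1e-6)
  expect_equal(sino[2, n / 2], 2 * R * 1e-6 * mu0, tolerance = 1e-6)
})

test_that("a centred disc projects identically at every angle", {
  n <- 64; pitch <- 10; disc <- disc_map(n, pitch, 20 * pitch, 1)
  ang <- projection_angles(36L)
  sino <- ray_transform(disc, ang, pitch)
  # total mass per projection is angle-invariant; profiles agree closely
  mass <- rowSums(sino)
  expect_lt(max(abs(mass - mean(mass))) / mean(mass), 1e-3)
  ref <- sino[1, ]
  for (a in seq_along(ang)) {
    expect_lt(max(abs(sino[a, ] - ref)) / max(ref), 0.05)
  }
})

test_that("projector agrees with a brute-force pixel-marching oracle", {
  n <- 32; pitch <- 7
  map <- matrix(0, n, n)
  map[9:16, 19:26] <- 2.5          # off-centre square
  angles <- c(0.37, 1.21, 2.53, 4.01)
  sino <- ray_transform(map, angles, pitch)
  for (a in seq_along(angles)) {
    oracle <- vapply(seq_len(n), function(d) {
      ray_integral_boxclip(map, angles[a], d, pitch)
    }, numeric(1))
    expect_lt(max(abs(sino[a, ] - oracle)) / max(oracle), 1e-6)
  }
})

test_that("opposite rays see the same line integrals", {
  ph <- build_vessel_phantom(test_vessel_spec(), MATS, 23)
  thetas <- c(0.3, 1.1, 2.2)
  s1 <- ray_transform(ph$mu_map, thetas, 5.4)
  s2 <- ray_transform(ph$mu_map, thetas + pi, 5.4)
  for (a in seq_along(thetas)) {
    expect_lt(max(abs(s1[a, ] - rev(s2[a, ]))) / max(s1[a, ]), 1e-3)
  }
})

test_that("differential phase vanishes for an edgeless field and is
           antisymmetric for a centred disc", {
  n <- 64; pitch <- 5.4
  geom <- synchrotron_geom()
  flat <- matrix(4e-7, n, n)
  # axis-aligned projections of a uniform slab: equal path on every ray
  phi <- differential_phase_projection(flat, c(0, pi / 2), geom, pitch)
  expect_equal(max(abs(phi)), 0)
  disc <- disc_map(n, pitch, 16 * pitch, 4.4e-7)
  phid <- differential_phase_projection(disc, c(0, pi / 4, 1.9), geom, pitch)
  for (a in 1:3) {
    asym <- phid[a, ] + rev(phid[a, ])
    expect_lt(max(abs(asym)) / max(abs(phid[a, ])), 0.02)
  }
})

test_that("differential phase tracks the analytic disc derivative", {
  n <- 128; pitch <- 5.4; R <- 32 * pitch; d0 <- 4.4e-7
  geom <- synchrotron_geom()
  disc <- disc_map_aa(n, pitch, R, d0)
  phi <- differential_phase_projection(disc, 0, geom, pitch)[1, ]
  t_um <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  scale <- 2 * pi * geom$phase_to_analyzer_cm * 1e-2 / (geom$p2_um * 1e-6)
  analytic <- -2 * d0 * (t_um * 1e-6) /
    sqrt(pmax((R * 1e-6)^2 - (t_um * 1e-6)^2, 1e-30)) * scale
  core <- abs(t_um) <= 0.8 * R     # away from the rim singularity
  expect_lt(max(abs(phi[core] - analytic[core])) / max(abs(analytic[core])),
            0.02)
})

test_that("transmission is the exponential of the attenuation integrals", {
  expect_equal(attenuation_to_transmission(0), 1)
  expect_equal(attenuation_to_transmission(log(2)), 0.5)
  x <- seq(0, 5, by = 0.25)
  expect_true(all(diff(attenuation_to_transmission(x)) < 0))
  expect_error(attenuation_to_transmission(-1), ">= 0")
})

test_that("stepping curves follow the cosine model in noiseless mode", {
  prot <- scan_protocol(n_projections = 1L, n_steps = 4L,
                        photons_per_pixel = 100, base_visibility = 0.3,
                        reference_every = 1L, n_reference = 1L,
                        noise = FALSE)
  Tm <- matrix(1, 1, 1); ph <- matrix(0, 1, 1)
  scan <- simulate_stepping(Tm, ph, 1, prot, psi_ref = 0)
  expect_equal(as.vector(scan$sample_frames[1, , 1]), c(130, 100, 70, 100))
  expect_error(simulate_stepping(Tm, ph, matrix(4, 1, 1),
                                 scan_protocol(1L, 4L, 100, 0.3,
                                               noise = FALSE)),
               "lie in")
  expect_error(simulate_stepping(matrix(1.5, 1, 1), ph, 1, prot),
               "lie in")
})

test_that("Poisson sampling has the right mean and variance and is
           reproducible", {
  prot <- scan_protocol(n_projections = 1L, n_steps = 4L,
                        photons_per_pixel = 1e4, base_visibility = 0.3,
                        reference_every = 1L, n_reference = 1L, seed = 42L)
  npx <- 10000L
  Tm <- matrix(0.8, 1, npx); ph <- matrix(0.4, 1, npx)
  scan <- simulate_stepping(Tm, ph, 1, prot, psi_ref = rep(0, npx))
  prot0 <- prot; prot0$noise <- FALSE
  clean <- simulate_stepping(Tm, ph, 1, prot0, psi_ref = rep(0, npx))
  for (k in 1:4) {
    mu <- clean$sample_frames[1, k, 1]
    expect_equal(mean(scan$sample_frames[1, k, ]), mu, tolerance = 0.01)
    expect_equal(var(scan$sample_frames[1, k, ]), mu, tolerance = 0.05)
  }
  again <- simulate_stepping(Tm, ph, 1, prot, psi_ref = rep(0, npx))
  expect_identical(scan$sample_frames, again$sample_frames)
  expect_identical(scan$reference_frames, again$reference_frames)
})
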