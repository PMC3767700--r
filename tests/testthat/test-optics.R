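test_that("wavelength conversion matches hand-computed values", {
  expect_equal(wavelength_from_energy(23), 5.390e-11, tolerance = 1e-3)
  expect_equal(wavelength_from_energy(22.8), 5.438e-11, tolerance = 1e-3)
  expect_equal(wavelength_from_energy(1.23984), 1.0e-9, tolerance = 1e-12)
  expect_error(wavelength_from_energy(0), "must be > 0")
  expect_error(wavelength_from_energy(-5), "must be > 0")
})

test_that("fractional Talbot distance reproduces the synchrotron spacing", {
  expect_equal(fractional_talbot_distance(4.8, 23, m = 9), 48.1,
               tolerance = 0.1 / 48.1)
  expect_equal(fractional_talbot_distance(4.8, 23, m = 1), 5.34,
               tolerance = 2e-3)
  # lambda ~ 1/E, so doubling E doubles the distance
  expect_equal(fractional_talbot_distance(4.8, 46, m = 1),
               2 * fractional_talbot_distance(4.8, 23, m = 1))
  expect_error(fractional_talbot_distance(4.8, 23, m = 2), "odd")
  expect_error(fractional_talbot_distance(4.8, 23, m = -3), "odd")
})

test_that("Talbot distance scales linearly in m and quadratically in p1", {
  for (p1 in c(2, 4.8, 5.4, 10)) {
    d1 <- fractional_talbot_distance(p1, 23, 1)
    for (m in c(3, 5, 9, 15)) {
      expect_equal(fractional_talbot_distance(p1, 23, m), m * d1,
                   tolerance = 1e-12)
    }
    expect_equal(fractional_talbot_distance(2 * p1, 23, 1), 4 * d1,
                 tolerance = 1e-12)
  }
})

test_that("the synchrotron spacing is the m = 9 Talbot order and no other", {
  rel_dev <- vapply(seq(1, 21, by = 2), function(m) {
    abs(fractional_talbot_distance(4.8, 23, m) - 48.1) / 48.1
  }, numeric(1))
  hits <- seq(1, 21, by = 2)[rel_dev <= 0.005]
  expect_identical(hits, 9)
})

test_that("grating period matching follows the fringe geometry", {
  expect_equal(required_analyzer_period(4.8, "parallel_two_grating"), 2.4)
  expect_equal(required_analyzer_period(5.4, "talbot_lau_symmetric"), 5.4)
  for (p1 in c(1, 3.7, 4.8, 12)) {
    expect_equal(required_analyzer_period(p1, "parallel_two_grating"),
                 p1 / 2)
  }
  expect_equal(required_source_period(5.4, 87.5, 87.5), 5.4)
  expect_equal(required_source_period(2, 100, 50), 4)
  # symmetric layout: p0 = p2 = p1 for a pi grating with fringe doubling
  for (p1 in c(2, 5.4, 8)) {
    p2 <- required_analyzer_period(p1, "talbot_lau_symmetric")
    expect_equal(required_source_period(p2, 87.5, 87.5), p1)
  }
  expect_error(required_analyzer_period(4.8, "ring_layout"))
})

test_that("magnification and effective pixel follow the distance ratios", {
  expect_equal(geometric_magnification(100, 172), 1.72)
  expect_equal(geometric_magnification(100, 100), 1.0)
  expect_error(geometric_magnification(172, 100), "between")
  expect_equal(effective_pixel(172, 1.72), 100)
})

test_that("grating phase shift hits pi for the nickel lamella design", {
  shift <- grating_phase_shift("nickel", 8, 22.8, MATS)
  expect_equal(shift, pi, tolerance = 0.01)
  expect_equal(grating_phase_shift("silicon", 29.5, 23, MATS), 3.13,
               tolerance = 5e-3)
  expect_equal(grating_phase_shift("nickel", 0, 22.8, MATS), 0)
  expect_error(grating_phase_shift("unobtainium", 8, 22.8, MATS), "unknown")
})

test_that("phase shift is linear in height and ~1/E in energy", {
  base <- grating_phase_shift("nickel", 4, 22.8, MATS)
  for (f in c(0.5, 2, 3.25)) {
    expect_equal(grating_phase_shift("nickel", 4 * f, 22.8, MATS), f * base,
                 tolerance = 1e-9)
  }
  # free-electron model: shift = r_e * lambda * n_e * h, so exactly ~ 1/E
  expect_equal(grating_phase_shift("nickel", 4, 45.6, MATS), base / 2,
               tolerance = 1e-9)
})

test_that("design report validates the synchrotron setup and flags the lab", {
  rep <- design_report(synchrotron_geom(),
                       phase_grating = grating_spec("silicon", 4.8, 29.5),
                       table = MATS)
  expect_true(rep$checks$distance_ok)
  expect_identical(rep$talbot_order, 9L)
  expect_equal(rep$required_p2_um, 2.4)

  # symmetric lab distance sits 0.4% from the 13th-order plane-wave
  # distance: marginal under the default 0.5% tolerance, flagged (warning,
  # not error) under a stricter one
  rep2 <- design_report(lab_geom(), detector_pixel_um = 172,
                        magnification = 1.72, table = MATS)
  expect_identical(rep2$talbot_order, 13L)
  expect_gt(rep2$checks$distance_rel_dev, 0.003)
  expect_lt(rep2$checks$distance_rel_dev, 0.005)
  expect_warning(rep3 <- design_report(lab_geom(), table = MATS,
                                       distance_tol = 0.002),
                 "Talbot")
  expect_false(rep3$checks$distance_ok)
  expect_equal(rep2$required_p2_um, 5.4)
  expect_equal(rep2$required_p0_um, 5.4)
  expect_equal(rep2$effective_pixel_um, 100)
})
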