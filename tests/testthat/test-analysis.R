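test_that("ROI SNR follows its definition and is offset/scale invariant", {
  img <- matrix(0, 20, 20)
  tis <- matrix(FALSE, 20, 20); tis[3:7, 3:7] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[12:18, 12:18] <- TRUE
  img[tis] <- 10
  img[bg] <- rep(c(1, -1), length.out = sum(bg))   # mean ~0, sd ~1
  s <- roi_snr(img, tis, bg)
  expect_equal(s$snr, abs(10 - s$mean_background) / s$sd_background)
  expect_equal(s$snr, 10 / s$sd_background, tolerance = 0.05)
  # equal-valued disjoint ROIs: zero contrast
  img2 <- img; img2[tis] <- img2[bg][seq_len(sum(tis))]
  expect_lt(roi_snr(img2, tis, bg)$snr, 0.2)
  # invariances of the ratio
  expect_equal(roi_snr(img + 5, tis, bg)$snr, s$snr)
  expect_equal(roi_snr(3 * img, tis, bg)$snr, s$snr, tolerance = 1e-12)
  expect_error(roi_snr(img, tis, tis), "disjoint")
  expect_error(roi_snr(matrix(1, 20, 20), tis, bg), "zero")
})

test_that("mask areas count pixels times pitch squared with derived rows", {
  m <- matrix(FALSE, 30, 30)
  lum <- m; lum[10:19, 10:19] <- TRUE                       # 100 px
  int <- m; int[5:9, 10:19] <- TRUE                         # 50 px
  med <- m; med[20:29, 10:19] <- TRUE                       # 100 px
  tab <- measure_areas(list(lumen = lum, intima = int, media = med), 100)
  expect_equal(tab$area_mm2[tab$region == "lumen"], 1.0)
  expect_equal(tab$area_mm2[tab$region == "intima"], 0.5)
  expect_equal(tab$area_mm2[tab$region == "wall"], 1.5)
  expect_equal(tab$area_mm2[tab$region == "total_vessel"], 2.5)
  over <- int; over[10, 10] <- TRUE
  expect_error(measure_areas(list(lumen = lum, intima = over), 100),
               "overlap")
  # 250 pixels at 100 um pitch -> 2.5 mm^2
  roi <- m; roi[1:10, 1:25] <- TRUE
  expect_equal(measure_areas(list(roi = roi), 100)$area_mm2, 2.5)
})

test_that("phantom self-measurement reproduces its ground-truth areas", {
  ph <- build_vessel_phantom(test_vessel_spec(), MATS, 23)
  masks <- lapply(c(lumen = "lumen", intima = "intima", media = "media",
                    adventitia = "adventitia"), function(rg) {
    ph$label_map == REGION_IDS[[rg]]
  })
  tab <- measure_areas(masks, ph$pixel_pitch_um, modality = "ground_truth")
  for (rg in names(masks)) {
    expect_identical(tab$area_mm2[tab$region == rg],
                     ph$areas$area_mm2[ph$areas$region == rg])
  }
})

test_that("ICC(A,1) agrees with an aov-based mean-squares oracle", {
  # worked 6-pair table
  r1 <- c(4.6, 2.1, 0.3, 1.8, 6.7, 3.2)
  r2 <- c(4.9, 2.0, 0.5, 1.9, 6.2, 3.4)
  expect_equal(icc_absolute_agreement(r1, r2), icc_oracle_aov(r1, r2),
               tolerance = 1e-12)
  # exhaustive sweep over small tables of every permitted size
  set.seed(99)
  for (n in 3:8) {
    for (rep in 1:5) {
      a <- rnorm(n, 10, 4)
      b <- a + rnorm(n, sd = runif(1, 0.05, 2)) + runif(1, -1, 1)
      expect_equal(icc_absolute_agreement(a, b), icc_oracle_aov(a, b),
                   tolerance = 1e-10)
    }
  }
})

test_that("ICC rewards agreement and penalizes a constant reader shift", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(icc_absolute_agreement(x, x), 1.0)
  shifted <- icc_absolute_agreement(x, x + 10)
  expect_lt(shifted, 1.0)
  expect_gt(shifted, -1.0)
  expect_error(icc_absolute_agreement(c(2, 2, 2), c(2, 2, 2)), "variance")
  expect_error(icc_absolute_agreement(1:2, 1:2), "at least 3")
})

test_that("slope regression predicts reference from measured areas", {
  x <- c(1, 2.5, 4, 6, 9)
  fit <- slope_vs_reference(x, x)
  expect_equal(fit$slope, 1.0)
  expect_lte(fit$ci[1], 1 + 1e-9)
  expect_gte(fit$ci[2], 1 - 1e-9)
  set.seed(3)
  xm <- runif(50, 1, 10)
  fit2 <- slope_vs_reference(xm, 0.5 * xm + rnorm(50, sd = 1e-8))
  expect_equal(fit2$slope, 0.5, tolerance = 1e-6)
  expect_error(slope_vs_reference(rep(2, 5), 1:5), "variance")
})

test_that("an unbiased noiseless reader reproduces the ground truth", {
  ph <- build_vessel_phantom(test_vessel_spec(), MATS, 23)
  tab <- reader_simulation(ph, bias = 0, boundary_noise_um = 0)
  for (rg in c("lumen", "intima", "media", "adventitia")) {
    expect_identical(tab$area_mm2[tab$region == rg],
                     ph$areas$area_mm2[ph$areas$region == rg])
  }
})

test_that("outward reader bias inflates every traced area", {
  ph <- build_vessel_phantom(test_vessel_spec(), MATS, 23)
  gt <- reader_simulation(ph, bias = 0, boundary_noise_um = 0)
  big <- reader_simulation(ph, bias = 0.08, boundary_noise_um = 0)
  for (rg in c("lumen", "intima", "media", "wall", "total_vessel")) {
    expect_gte(big$area_mm2[big$region == rg],
               gt$area_mm2[gt$region == rg])
  }
  # wall stays the sum of its parts after perturbation
  expect_equal(big$area_mm2[big$region == "wall"],
               sum(big$area_mm2[big$region %in% c("intima", "media")]),
               tolerance = 1e-12)
  # multiplicative radial bias scales areas by about (1 + bias)^2
  ratio <- big$area_mm2[big$region == "total_vessel"] /
    gt$area_mm2[gt$region == "total_vessel"]
  expect_equal(ratio, 1.08^2, tolerance = 0.02)
})

test_that("a reader with systematic 20% area overestimation yields a slope
           near 1/1.2 against ground truth", {
  bias <- sqrt(1.2) - 1
  sizes <- seq(0.6, 1.2, length.out = 10)
  measured <- c(); reference <- c()
  for (i in seq_along(sizes)) {
    spec <- vessel_spec(grid_size = 96L, pixel_pitch_um = 5.4,
                        lumen_semi_axes_um = sizes[i] * c(80, 70),
                        layer_thickness_um = sizes[i] *
                          c(intima = 22, media = 40, adventitia = 25),
                        jitter_um = 2, seed = i)
    ph <- build_vessel_phantom(spec, MATS, 23)
    tab <- reader_simulation(ph, bias = bias, boundary_noise_um = 0.5,
                             seed = 100 + i)
    gt <- phantom_to_ground_truth_report(ph)
    for (rg in c("lumen", "wall", "total_vessel")) {
      measured <- c(measured, tab$area_mm2[tab$region == rg])
      reference <- c(reference, gt$area_mm2[gt$region == rg])
    }
  }
  fit <- slope_vs_reference(measured, reference)
  expect_equal(fit$slope, 1 / 1.2, tolerance = 0.05)
})
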