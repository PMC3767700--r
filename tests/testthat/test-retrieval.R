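test_that("first-harmonic analysis matches hand DFT results", {
  fit <- fit_stepping_curve(c(130, 100, 70, 100))
  expect_equal(fit$a0, 100)
  expect_equal(fit$a1, 30)
  expect_equal(fit$ph1, 0)
  # one-step cyclic shift moves the first-harmonic phase by -pi/2
  fit2 <- fit_stepping_curve(c(100, 130, 100, 70))
  expect_equal(fit2$a0, 100)
  expect_equal(fit2$a1, 30)
  expect_equal(fit2$ph1, -pi / 2)
  flat <- fit_stepping_curve(c(50, 50, 50, 50))
  expect_equal(flat$a0, 50)
  expect_equal(flat$a1, 0)
  expect_true(flat$flagged)
  expect_error(fit_stepping_curve(c(1, 2)), "at least 3")
})

test_that("flat-fielding the reference against itself is the identity", {
  prot <- scan_protocol(n_projections = 4L, n_steps = 4L,
                        photons_per_pixel = 1000, base_visibility = 0.3,
                        reference_every = 2L, n_reference = 2L,
                        noise = FALSE)
  nd <- 16L
  Tm <- matrix(1, 4, nd); ph <- matrix(0, 4, nd)
  scan <- simulate_stepping(Tm, ph, 1, prot)
  out <- retrieve_scan(scan)
  expect_equal(max(abs(out$transmission - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(out$dphase)), 0, tolerance = 1e-12)
  expect_equal(max(abs(out$darkfield - 1)), 0, tolerance = 1e-12)
  expect_true(all(out$mask))
})

test_that("noiseless simulate -> retrieve is the identity for any K >= 3", {
  set.seed(31)
  for (K in c(3L, 4L, 11L)) {
    na <- 8L; nd <- 24L
    Tm <- matrix(runif(na * nd, 0.3, 1), na, nd)
    ph <- matrix(runif(na * nd, -3, 3), na, nd)
    D <- matrix(runif(na * nd, 0.5, 1), na, nd)
    prot <- scan_protocol(n_projections = na, n_steps = K,
                          photons_per_pixel = 1e4, base_visibility = 0.6,
                          reference_every = 3L, n_reference = 2L,
                          noise = FALSE)
    scan <- simulate_stepping(Tm, ph, D, prot)
    out <- retrieve_scan(scan)
    expect_lt(max(abs(out$transmission - Tm) / Tm), 1e-12)
    expect_lt(max(abs(out$dphase - wrap_phase(ph))), 1e-11)
    expect_lt(max(abs(out$darkfield - D) / D), 1e-11)
  }
})

test_that("the two study stepping protocols retrieve identically without
           noise", {
  na <- 6L; nd <- 20L
  set.seed(7)
  Tm <- matrix(runif(na * nd, 0.4, 1), na, nd)
  ph <- matrix(runif(na * nd, -2, 2), na, nd)
  outs <- lapply(c(4L, 11L), function(K) {
    prot <- scan_protocol(n_projections = na, n_steps = K,
                          photons_per_pixel = 1e4, base_visibility = 0.3,
                          reference_every = 2L, n_reference = 2L,
                          noise = FALSE)
    retrieve_scan(simulate_stepping(Tm, ph, 1, prot))
  })
  expect_equal(outs[[1]]$transmission, outs[[2]]$transmission,
               tolerance = 1e-12)
  expect_equal(outs[[1]]$dphase, outs[[2]]$dphase, tolerance = 1e-12)
})

test_that("retrieved phase wraps into (-pi, pi]", {
  prot <- scan_protocol(n_projections = 1L, n_steps = 4L,
                        photons_per_pixel = 1e4, base_visibility = 0.3,
                        reference_every = 1L, n_reference = 1L,
                        noise = FALSE)
  ph <- matrix(pi + 0.3, 1, 8)
  scan <- simulate_stepping(matrix(1, 1, 8), ph, 1, prot)
  out <- retrieve_scan(scan)
  expect_equal(out$dphase[1, ], rep(-pi + 0.3, 8), tolerance = 1e-12)
  expect_true(all(out$dphase > -pi & out$dphase <= pi))
})

test_that("low reference visibility masks pixels instead of throwing", {
  prot <- scan_protocol(n_projections = 2L, n_steps = 4L,
                        photons_per_pixel = 1000,
                        base_visibility = 1e-4,    # below the 0.5% floor
                        reference_every = 1L, n_reference = 1L,
                        noise = FALSE)
  scan <- simulate_stepping(matrix(0.9, 2, 6), matrix(0.2, 2, 6), 1, prot)
  out <- retrieve_scan(scan)
  expect_true(all(!out$mask))
  expect_true(all(is.na(out$transmission)))
})

test_that("1D unwrapping undoes 2*pi jumps and round-trips with wrapping", {
  ramp <- seq(0, 4.7, length.out = 60)        # crosses +pi once
  wrapped <- wrap_phase(ramp)
  expect_equal(unwrap_dphase(wrapped), ramp, tolerance = 1e-12)
  smooth <- 0.8 * sin(seq(0, 2 * pi, length.out = 40))
  expect_equal(unwrap_dphase(smooth), smooth)  # no jumps: unchanged
  set.seed(5)
  x <- cumsum(rnorm(50, sd = 0.5))
  expect_equal(wrap_phase(unwrap_dphase(wrap_phase(x))), wrap_phase(x),
               tolerance = 1e-12)
})

test_that("retrieved-phase noise falls as one over the square root of the
           photon budget", {
  i0s <- c(1e2, 1e3, 1e4)
  sds <- vapply(seq_along(i0s), function(i) {
    prot <- scan_protocol(n_projections = 1L, n_steps = 4L,
                          photons_per_pixel = i0s[i], base_visibility = 0.3,
                          reference_every = 1L, n_reference = 10L,
                          seed = 100L + i)
    nd <- 1000L
    scan <- simulate_stepping(matrix(1, 1, nd), matrix(0.5, 1, nd), 1, prot)
    out <- retrieve_scan(scan)
    sd(out$dphase[1, ])
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(i0s)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.1)
})
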