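# Shared fixtures and independent oracles.

MATS <- default_materials()

synchrotron_geom <- function() {
  geometry_config("parallel_two_grating", phase_to_analyzer_cm = 48.1,
                  design_energy_kev = 23, p1_um = 4.8, talbot_order = 9)
}

lab_geom <- function() {
  suppressWarnings(
    geometry_config("talbot_lau_symmetric", phase_to_analyzer_cm = 87.5,
                    source_to_phase_cm = 87.5, design_energy_kev = 22.8,
                    p1_um = 5.4))
}

grid_radius <- function(n, pitch_um) {
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * pitch_um
  sqrt(outer(ax^2, ax^2, `+`))
}

disc_map <- function(n, pitch_um, radius_um, value, outside = 0) {
  r <- grid_radius(n, pitch_um)
  ifelse(r <= radius_um, value, outside)
}

# disc with exact-area rim coverage (supersampled), for comparisons against
# smooth closed-form projections
disc_map_aa <- function(n, pitch_um, radius_um, value, ss = 16L) {
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * pitch_um
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  r <- sqrt(X^2 + Y^2)
  cov <- (r <= radius_um) + 0
  off <- (seq_len(ss) - (ss + 1) / 2) / ss * pitch_um
  for (idx in which(abs(r - radius_um) < pitch_um)) {
    cov[idx] <- mean(outer((X[idx] + off)^2, (Y[idx] + off)^2, `+`) <=
                       radius_um^2)
  }
  value * cov
}

# Brute-force pixel-marching line integral: clip the ray against every pixel
# box (Liang-Barsky slab test) and sum exact intersection lengths. Exact for
# the piecewise-constant pixel image; independent of the C++ traversal.
ray_integral_boxclip <- function(map, theta, det_index, pitch_um) {
  n <- nrow(map)
  h <- n / 2
  ct <- cos(theta); st <- sin(theta)
  t <- det_index - 1 - (n - 1) / 2   # detector coordinate, pixel units
  total <- 0
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1)) {
      v <- map[i + 1, j + 1]
      if (v == 0) next
      x0 <- i - h; x1 <- i + 1 - h
      y0 <- j - h; y1 <- j + 1 - h
      lo <- -Inf; hi <- Inf; ok <- TRUE
      if (abs(st) > 1e-14) {
        s1 <- (t * ct - x0) / st; s2 <- (t * ct - x1) / st
        lo <- max(lo, min(s1, s2)); hi <- min(hi, max(s1, s2))
      } else if (t * ct < x0 || t * ct > x1) ok <- FALSE
      if (abs(ct) > 1e-14) {
        s1 <- (y0 - t * st) / ct; s2 <- (y1 - t * st) / ct
        lo <- max(lo, min(s1, s2)); hi <- min(hi, max(s1, s2))
      } else if (t * st < y0 || t * st > y1) ok <- FALSE
      if (ok && hi > lo) total <- total + v * (hi - lo)
    }
  }
  total * pitch_um * 1e-6
}

# ICC(A,1) oracle: mean squares pulled from a stats::aov two-way fit.
icc_oracle_aov <- function(r1, r2) {
  n <- length(r1)
  d <- data.frame(y = c(r1, r2),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ target + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small test phantom: round vessel on a coarse grid, fast to build
test_vessel_spec <- function(grid_size = 96L, jitter_um = 3, seed = 1L,
                             inclusions = list()) {
  vessel_spec(grid_size = grid_size, pixel_pitch_um = 5.4,
              lumen_semi_axes_um = c(80, 70),
              layer_thickness_um = c(intima = 22, media = 40,
                                     adventitia = 25),
              inclusions = inclusions, jitter_um = jitter_um, seed = seed)
}
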