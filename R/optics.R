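#' X-ray wavelength from photon energy
#'
#' Converts a photon energy in keV to a wavelength in meters via
#' lambda = hc/E with hc = 1.23984 keV*nm.
#'
#' @param energy_kev photon energy in keV (> 0).
#' @return wavelength in meters.
#' @examples
#' wavelength_from_energy(23)    # ~5.39e-11 m
#' @export
wavelength_from_energy <- function(energy_kev) {
  .check_number(energy_kev, "energy_kev")
  HC_KEV_M / energy_kev
}

.check_odd_order <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m <= 0 ||
      m != round(m) || (m %% 2) != 1) {
    .stopf("Talbot order `m` must be a positive odd integer (got %s)",
           paste(m, collapse = ","))
  }
  invisible(as.integer(m))
}

#' Fractional Talbot distance of a pi-shifting phase grating
#'
#' For a phase grating of period `p1` that imprints a pi phase shift under
#' plane-wave illumination, intensity fringes of period p1/2 form at the odd
#' fractional Talbot distances d_m = m * p1^2 / (8 * lambda).
#'
#' @param p1_um phase-grating period in micrometers.
#' @param energy_kev design energy in keV.
#' @param m odd positive Talbot order.
#' @return distance in centimeters.
#' @examples
#' fractional_talbot_distance(4.8, 23, m = 9)   # ~48.1 cm
#' @export
fractional_talbot_distance <- function(p1_um, energy_kev, m = 1L) {
  .check_number(p1_um, "p1_um")
  m <- .check_odd_order(m)
  lambda <- wavelength_from_energy(energy_kev)
  p1 <- p1_um * 1e-6
  100 * m * p1^2 / (8 * lambda)
}

#' Analyzer-grating period required to sample the fringe pattern
#'
#' A pi-shifting phase grating produces a fringe period of half its own
#' period; in a magnifying geometry the fringe is stretched by the geometric
#' magnification of the fringe pattern (2 in the symmetric Talbot-Lau layout,
#' 1 for a parallel plane-wave beam).
#'
#' @param p1_um phase-grating period in micrometers.
#' @param layout `"parallel_two_grating"` or `"talbot_lau_symmetric"`.
#' @param magnification fringe magnification; defaults to 1 for the parallel
#'   layout and 2 for the symmetric Talbot-Lau layout.
#' @return analyzer period p2 in micrometers (M * p1 / 2).
#' @examples
#' required_analyzer_period(4.8, "parallel_two_grating")   # 2.4
#' required_analyzer_period(5.4, "talbot_lau_symmetric")   # 5.4
#' @export
required_analyzer_period <- function(p1_um,
                                     layout = c("parallel_two_grating",
                                                "talbot_lau_symmetric"),
                                     magnification = NULL) {
  .check_number(p1_um, "p1_um")
  layout <- match.arg(layout)
  if (is.null(magnification)) {
    magnification <- switch(layout,
                            parallel_two_grating = 1,
                            talbot_lau_symmetric = 2)
  }
  .check_number(magnification, "magnification")
  magnification * p1_um / 2
}

#' Source-grating period from the Talbot-Lau matching condition
#'
#' The slit array G0 must project fringe patterns from each slit that add
#' constructively at the analyzer plane: p0 = p2 * l / d, with `l` the
#' source-to-phase-grating distance and `d` the phase-to-analyzer distance.
#'
#' @param p2_um analyzer period in micrometers.
#' @param source_to_phase_cm distance G0 -> G1 in cm.
#' @param phase_to_analyzer_cm distance G1 -> G2 in cm.
#' @return source-grating period p0 in micrometers.
#' @examples
#' required_source_period(5.4, 87.5, 87.5)  # symmetric: 5.4
#' @export
required_source_period <- function(p2_um, source_to_phase_cm,
                                   phase_to_analyzer_cm) {
  .check_number(p2_um, "p2_um")
  .check_number(source_to_phase_cm, "source_to_phase_cm")
  .check_number(phase_to_analyzer_cm, "phase_to_analyzer_cm")
  p2_um * source_to_phase_cm / phase_to_analyzer_cm
}

#' Geometric magnification of a point-source projection
#'
#' @param source_to_sample_cm distance source -> sample in cm.
#' @param source_to_detector_cm distance source -> detector in cm
#'   (must be >= `source_to_sample_cm`).
#' @return dimensionless magnification >= 1.
#' @export
geometric_magnification <- function(source_to_sample_cm,
                                    source_to_detector_cm) {
  .check_number(source_to_sample_cm, "source_to_sample_cm")
  .check_number(source_to_detector_cm, "source_to_detector_cm")
  if (source_to_sample_cm > source_to_detector_cm) {
    .stopf("sample must lie between source and detector")
  }
  source_to_detector_cm / source_to_sample_cm
}

#' Effective (sample-plane) pixel size
#'
#' @param detector_pixel_um physical detector pixel size in micrometers.
#' @param magnification geometric magnification of the sample.
#' @return effective pixel size in micrometers.
#' @examples
#' effective_pixel(172, 1.72)  # 100
#' @export
effective_pixel <- function(detector_pixel_um, magnification) {
  .check_number(detector_pixel_um, "detector_pixel_um")
  .check_number(magnification, "magnification")
  if (magnification < 1) .stopf("magnification must be >= 1")
  detector_pixel_um / magnification
}

#' Phase shift imprinted by a grating lamella
#'
#' Phase advance of a wave crossing a lamella of height `h`:
#' (2*pi/lambda) * delta(material, E) * h, with delta from the free-electron
#' model of the materials table.
#'
#' @param material material name (must be registered in `table`).
#' @param height_um lamella height in micrometers (>= 0).
#' @param energy_kev design energy in keV.
#' @param table a material table, see [default_materials()].
#' @return phase shift in radians.
#' @examples
#' grating_phase_shift("nickel", 8, 22.8)    # ~pi
#' @export
grating_phase_shift <- function(material, height_um, energy_kev,
                                table = default_materials()) {
  .check_number(height_um, "height_um", positive = FALSE)
  if (height_um < 0) .stopf("height_um must be >= 0")
  mat <- get_material(material, table)
  delta <- delta_free_electron(mat, energy_kev)
  lambda <- wavelength_from_energy(energy_kev)
  (2 * pi / lambda) * delta * height_um * 1e-6
}

#' Grating specification
#'
#' @param material material name.
#' @param period_um grating period in micrometers (> 0).
#' @param lamella_height_um lamella height in micrometers (>= 0).
#' @param role one of `"source"`, `"phase"`, `"analyzer"`.
#' @return an object of class `grating_spec`.
#' @export
grating_spec <- function(material, period_um, lamella_height_um,
                         role = c("phase", "source", "analyzer")) {
  role <- match.arg(role)
  .check_number(period_um, "period_um")
  .check_number(lamella_height_um, "lamella_height_um", positive = FALSE)
  if (lamella_height_um < 0) .stopf("lamella_height_um must be >= 0")
  structure(list(material = material, period_um = period_um,
                 lamella_height_um = lamella_height_um, role = role),
            class = "grating_spec")
}

#' Interferometer geometry configuration
#'
#' Describes either a two-grating parallel-beam layout (synchrotron-style,
#' no source grating) or a symmetric three-grating Talbot-Lau layout.
#'
#' @param layout `"parallel_two_grating"` or `"talbot_lau_symmetric"`.
#' @param phase_to_analyzer_cm inter-grating distance d (G1 -> G2) in cm.
#' @param design_energy_kev design energy in keV.
#' @param p1_um phase-grating period in micrometers.
#' @param source_to_phase_cm distance l (G0 -> G1) in cm; required (and equal
#'   to d) for the symmetric Talbot-Lau layout.
#' @param talbot_order odd positive design order, or `NA` when unknown.
#' @param p2_um analyzer period in micrometers; defaults to
#'   [required_analyzer_period()].
#' @return an object of class `geometry_config`.
#' @export
geometry_config <- function(layout = c("parallel_two_grating",
                                       "talbot_lau_symmetric"),
                            phase_to_analyzer_cm, design_energy_kev, p1_um,
                            source_to_phase_cm = NULL, talbot_order = NA,
                            p2_um = NULL) {
  layout <- match.arg(layout)
  .check_number(phase_to_analyzer_cm, "phase_to_analyzer_cm")
  .check_number(design_energy_kev, "design_energy_kev")
  .check_number(p1_um, "p1_um")
  if (!is.na(talbot_order)) .check_odd_order(talbot_order)
  if (layout == "talbot_lau_symmetric") {
    if (is.null(source_to_phase_cm)) source_to_phase_cm <- phase_to_analyzer_cm
    .check_number(source_to_phase_cm, "source_to_phase_cm")
    if (abs(source_to_phase_cm - phase_to_analyzer_cm) >
        1e-9 * phase_to_analyzer_cm) {
      .stopf("symmetric Talbot-Lau layout requires l = d")
    }
  }
  if (is.null(p2_um)) p2_um <- required_analyzer_period(p1_um, layout)
  structure(list(layout = layout,
                 source_to_phase_cm = source_to_phase_cm,
                 phase_to_analyzer_cm = phase_to_analyzer_cm,
                 design_energy_kev = design_energy_kev,
                 talbot_order = talbot_order,
                 p1_um = p1_um, p2_um = p2_um),
            class = "geometry_config")
}

#' Design report for an interferometer configuration
#'
#' Evaluates the closed-form design quantities for a geometry and (optionally)
#' checks the inter-grating distance against the odd fractional Talbot
#' condition. For the symmetric Talbot-Lau layout a failed distance check
#' produces a warning rather than an error (tube-source designs trade the
#' strict plane-wave condition against source size and flux).
#'
#' @param geometry a [geometry_config()].
#' @param phase_grating optional [grating_spec()] for the phase grating, used
#'   to evaluate its phase shift at the design energy.
#' @param detector_pixel_um physical detector pixel in micrometers (optional).
#' @param magnification sample magnification (default 1).
#' @param table material table for the phase-shift evaluation.
#' @param distance_tol relative tolerance for the Talbot-distance check.
#' @return an object of class `design_report` with fields `wavelength_m`,
#'   `talbot_distance_cm`, `required_p2_um`, `required_p0_um`,
#'   `magnification`, `effective_pixel_um`, `phase_shift_rad`, `checks`.
#' @export
design_report <- function(geometry, phase_grating = NULL,
                          detector_pixel_um = NULL, magnification = 1,
                          table = default_materials(),
                          distance_tol = 0.005) {
  stopifnot(inherits(geometry, "geometry_config"))
  lambda <- wavelength_from_energy(geometry$design_energy_kev)
  p2 <- required_analyzer_period(geometry$p1_um, geometry$layout)
  p0 <- if (geometry$layout == "talbot_lau_symmetric") {
    required_source_period(p2, geometry$source_to_phase_cm,
                           geometry$phase_to_analyzer_cm)
  } else NA_real_

  # nearest odd-order Talbot distance to the configured d
  orders <- seq(1L, 41L, by = 2L)
  dists <- vapply(orders, function(m) {
    fractional_talbot_distance(geometry$p1_um, geometry$design_energy_kev, m)
  }, numeric(1))
  rel <- abs(dists - geometry$phase_to_analyzer_cm) /
    geometry$phase_to_analyzer_cm
  best <- which.min(rel)
  distance_ok <- rel[best] <= distance_tol
  if (!distance_ok) {
    msg <- sprintf(paste0("inter-grating distance %.2f cm is not within %.2g ",
                          "of any odd fractional Talbot distance ",
                          "(closest: m=%d at %.2f cm)"),
                   geometry$phase_to_analyzer_cm, distance_tol,
                   orders[best], dists[best])
    if (geometry$layout == "talbot_lau_symmetric") warning(msg, call. = FALSE)
    else .stopf("%s", msg)
  }

  shift <- if (!is.null(phase_grating)) {
    grating_phase_shift(phase_grating$material,
                        phase_grating$lamella_height_um,
                        geometry$design_energy_kev, table)
  } else NA_real_
  eff <- if (!is.null(detector_pixel_um)) {
    effective_pixel(detector_pixel_um, magnification)
  } else NA_real_

  structure(list(wavelength_m = lambda,
                 talbot_distance_cm = dists[best],
                 talbot_order = orders[best],
                 required_p2_um = p2,
                 required_p0_um = p0,
                 magnification = magnification,
                 effective_pixel_um = eff,
                 phase_shift_rad = shift,
                 checks = list(distance_ok = distance_ok,
                               distance_rel_dev = rel[best])),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat("Interferometer design report\n")
  cat(sprintf("  wavelength        : %.4e m\n", x$wavelength_m))
  cat(sprintf("  Talbot distance   : %.2f cm (order m=%d)\n",
              x$talbot_distance_cm, x$talbot_order))
  cat(sprintf("  required p2       : %.3f um\n", x$required_p2_um))
  if (!is.na(x$required_p0_um)) {
    cat(sprintf("  required p0       : %.3f um\n", x$required_p0_um))
  }
  if (!is.na(x$effective_pixel_um)) {
    cat(sprintf("  magnification     : %.3f\n", x$magnification))
    cat(sprintf("  effective pixel   : %.1f um\n", x$effective_pixel_um))
  }
  if (!is.na(x$phase_shift_rad)) {
    cat(sprintf("  phase shift       : %.4f rad (pi = %.4f)\n",
                x$phase_shift_rad, pi))
  }
  cat(sprintf("  distance check    : %s (rel. dev. %.3g)\n",
              if (x$checks$distance_ok) "ok" else "FAILED",
              x$checks$distance_rel_dev))
  invisible(x)
}
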