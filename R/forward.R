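#' Tomographic scan protocol
#'
#' @param n_projections number of projections over 360 degrees.
#' @param n_steps number of phase steps K per projection (>= 3; the stepping
#'   spans exactly one grating period in K equal steps).
#' @param photons_per_pixel mean photon count I0 per detector pixel per frame
#'   in the absence of the sample.
#' @param base_visibility interferometer visibility V0 in (0, 1].
#' @param reference_every number of projections between reference (flat)
#'   blocks.
#' @param n_reference number of reference stepping scans per block.
#' @param seed RNG seed for the Poisson noise.
#' @param noise logical; `FALSE` gives noiseless expected intensities.
#' @return an object of class `scan_protocol`.
#' @export
scan_protocol <- function(n_projections = 360L, n_steps = 4L,
                          photons_per_pixel = 1e4, base_visibility = 0.3,
                          reference_every = 100L, n_reference = 10L,
                          seed = 1L, noise = TRUE) {
  if (n_steps < 3) .stopf("at least 3 phase steps are required")
  if (n_projections < 1) .stopf("n_projections must be >= 1")
  .check_number(photons_per_pixel, "photons_per_pixel")
  if (base_visibility <= 0 || base_visibility > 1) {
    .stopf("base_visibility must lie in (0, 1]")
  }
  structure(list(n_projections = as.integer(n_projections),
                 n_steps = as.integer(n_steps),
                 photons_per_pixel = photons_per_pixel,
                 base_visibility = base_visibility,
                 reference_every = as.integer(reference_every),
                 n_reference = as.integer(n_reference),
                 seed = as.integer(seed), noise = isTRUE(noise)),
            class = "scan_protocol")
}

#' Projection angles for a protocol
#'
#' Uniform angles over \[0, 2*pi), counterclockwise from the +x detector axis.
#'
#' @param n_projections number of projections (or a [scan_protocol()]).
#' @return numeric vector of angles in radians.
#' @export
projection_angles <- function(n_projections) {
  if (inherits(n_projections, "scan_protocol")) {
    n_projections <- n_projections$n_projections
  }
  seq(0, 2 * pi, length.out = n_projections + 1L)[seq_len(n_projections)]
}

#' Parallel-beam ray transform (line integrals)
#'
#' Line integrals of a square 2D map along parallel rays, computed with
#' Joseph's method (interpolation along the dominant ray axis). Output units
#' are the map's units times meters.
#'
#' @param map2d square numeric matrix; first index along +x, second along +y.
#' @param angles projection angles in radians in \[0, 2*pi).
#' @param pitch_um pixel and detector pitch in micrometers.
#' @param n_det number of detector bins (default: image size).
#' @return sinogram matrix (angle x detector).
#' @export
ray_transform <- function(map2d, angles, pitch_um, n_det = nrow(map2d)) {
  if (length(angles) == 0) .stopf("at least one projection angle is required")
  if (!is.matrix(map2d) || nrow(map2d) != ncol(map2d)) {
    .stopf("map2d must be a square matrix")
  }
  .check_number(pitch_um, "pitch_um")
  cpp_forward_project(map2d, as.numeric(angles), as.integer(n_det),
                      pitch_um * 1e-6)
}

#' Differential phase projection of a delta map
#'
#' Refraction by the sample tilts the wavefront by the transverse derivative
#' of the accumulated phase; at the analyzer plane this appears as a stepping
#' phase phi(theta, t) = (2*pi*d_s / p2) * d/dt \[integral of delta dz\],
#' where d_s is the phase-to-analyzer distance and p2 the analyzer period.
#' The transverse derivative is taken by central differences at detector
#' pitch (one-sided at the detector edges).
#'
#' @param delta_map square matrix of refractive-index decrements.
#' @param angles projection angles in radians.
#' @param geometry a [geometry_config()] supplying d_s and p2.
#' @param pitch_um detector pitch in micrometers.
#' @param n_det number of detector bins.
#' @return phi sinogram in radians (angle x detector), unwrapped.
#' @export
differential_phase_projection <- function(delta_map, angles, geometry,
                                          pitch_um, n_det = nrow(delta_map)) {
  stopifnot(inherits(geometry, "geometry_config"))
  P <- ray_transform(delta_map, angles, pitch_um, n_det)  # in m
  dP <- .transverse_derivative(P, pitch_um * 1e-6)        # d/dt, 1/m units
  d_s <- geometry$phase_to_analyzer_cm * 1e-2
  p2 <- geometry$p2_um * 1e-6
  (2 * pi * d_s / p2) * dP
}

# central differences along the detector axis (columns), one-sided at edges
.transverse_derivative <- function(sino, pitch_m) {
  nd <- ncol(sino)
  if (nd < 3) .stopf("need at least 3 detector bins for a derivative")
  d <- sino
  d[, 2:(nd - 1)] <- (sino[, 3:nd] - sino[, 1:(nd - 2)]) / (2 * pitch_m)
  d[, 1] <- (sino[, 2] - sino[, 1]) / pitch_m
  d[, nd] <- (sino[, nd] - sino[, nd - 1]) / pitch_m
  d
}

#' Transmission from attenuation line integrals
#'
#' @param mu_sinogram line integrals of mu (dimensionless, i.e. 1/m times m).
#' @return transmission T = exp(-integral), in (0, 1].
#' @export
attenuation_to_transmission <- function(mu_sinogram) {
  if (any(mu_sinogram < -1e-9)) {
    .stopf("attenuation line integrals must be >= 0")
  }
  exp(-pmax(mu_sinogram, 0))
}

#' Simulate a phase-stepping acquisition
#'
#' Generates per-pixel stepping curves for every projection,
#' `I_k = I0 * T * (1 + V0 * D * cos(2*pi*k/K - (phi + psi_ref)))`, plus
#' interleaved reference (flat-field) blocks
#' `I_k = I0 * (1 + V0 * cos(2*pi*k/K - psi_ref))`, each Poisson-sampled
#' under the protocol seed when `protocol$noise` is `TRUE`. The reference
#' (moire) phase map `psi_ref` defaults to a small linear ramp across the
#' detector so flat-field correction is exercised nontrivially.
#'
#' @param T_sino transmission sinogram in (0, 1\] (angle x detector).
#' @param phi_sino differential-phase sinogram in radians (same shape).
#' @param D_sino dark-field visibility-reduction sinogram in (0, 1\];
#'   scalar 1 means no small-angle scattering.
#' @param protocol a [scan_protocol()].
#' @param geometry a [geometry_config()] (carried for provenance).
#' @param psi_ref reference phase per detector pixel; default ramp 0..0.5 rad.
#' @return an object of class `stepping_scan` with `sample_frames`
#'   (angle x step x pixel), `reference_frames` (block x repeat x step x
#'   pixel), `block_projections`, `angles`, `psi_ref`, `protocol`, `geometry`.
#' @export
simulate_stepping <- function(T_sino, phi_sino, D_sino = 1, protocol,
                              geometry = NULL, psi_ref = NULL) {
  stopifnot(inherits(protocol, "scan_protocol"))
  na <- nrow(T_sino); nd <- ncol(T_sino)
  if (!all(dim(phi_sino) == c(na, nd))) .stopf("sinogram shapes differ")
  if (length(D_sino) == 1) D_sino <- matrix(D_sino, na, nd)
  if (!all(dim(D_sino) == c(na, nd))) .stopf("sinogram shapes differ")
  if (any(!is.finite(phi_sino))) .stopf("phi sinogram must be finite")
  if (any(T_sino <= 0) || any(T_sino > 1 + 1e-9)) {
    .stopf("transmission must lie in (0, 1]")
  }
  if (any(D_sino <= 0) || any(D_sino > 1 + 1e-9)) {
    .stopf("dark-field D must lie in (0, 1]")
  }
  if (protocol$base_visibility * max(D_sino) > 1) {
    .stopf("V0 * D > 1 would produce negative intensities")
  }
  if (is.null(psi_ref)) psi_ref <- seq(0, 0.5, length.out = nd)
  stopifnot(length(psi_ref) == nd)

  K <- protocol$n_steps
  I0 <- protocol$photons_per_pixel
  V0 <- protocol$base_visibility
  steps <- 2 * pi * (seq_len(K) - 1) / K
  psi_mat <- matrix(psi_ref, na, nd, byrow = TRUE)

  sample_frames <- array(0, dim = c(na, K, nd))
  for (k in seq_len(K)) {
    sample_frames[, k, ] <- I0 * T_sino *
      (1 + V0 * D_sino * cos(steps[k] - (phi_sino + psi_mat)))
  }

  block_projections <- seq(1L, protocol$n_projections,
                           by = protocol$reference_every)
  nb <- length(block_projections)
  reference_frames <- array(0, dim = c(nb, protocol$n_reference, K, nd))
  ref_curve <- sapply(seq_len(K), function(k) {
    I0 * (1 + V0 * cos(steps[k] - psi_ref))
  })  # nd x K
  for (b in seq_len(nb)) {
    for (rrep in seq_len(protocol$n_reference)) {
      reference_frames[b, rrep, , ] <- t(ref_curve)
    }
  }

  if (protocol$noise) {
    set.seed(protocol$seed)
    sample_frames[] <- stats::rpois(length(sample_frames), sample_frames)
    reference_frames[] <- stats::rpois(length(reference_frames),
                                       reference_frames)
  }

  structure(list(sample_frames = sample_frames,
                 reference_frames = reference_frames,
                 block_projections = block_projections,
                 angles = projection_angles(na),
                 psi_ref = psi_ref, protocol = protocol, geometry = geometry),
            class = "stepping_scan")
}

#' Forward-simulate a full scan of a phantom
#'
#' Convenience wrapper: ray transforms of the mu and delta maps, conversion
#' to transmission and differential phase, then [simulate_stepping()].
#'
#' @param phantom a [build_vessel_phantom()] result.
#' @param protocol a [scan_protocol()].
#' @param geometry a [geometry_config()].
#' @param D_sino dark-field ground truth (default 1, no scattering).
#' @param psi_ref optional reference phase map.
#' @return a `stepping_scan`; the noiseless ground-truth sinograms are
#'   attached as attribute `"truth"` (list `T`, `phi`).
#' @export
simulate_scan <- function(phantom, protocol, geometry, D_sino = 1,
                          psi_ref = NULL) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  angles <- projection_angles(protocol)
  mu_li <- ray_transform(phantom$mu_map, angles, phantom$pixel_pitch_um)
  T_sino <- attenuation_to_transmission(mu_li)
  phi_sino <- differential_phase_projection(phantom$delta_map, angles,
                                            geometry, phantom$pixel_pitch_um)
  scan <- simulate_stepping(T_sino, phi_sino, D_sino, protocol, geometry,
                            psi_ref)
  attr(scan, "truth") <- list(T = T_sino, phi = phi_sino)
  scan
}

#' Write a stepping scan to disk
#'
#' Sample frames are stored as a multi-page float TIFF (one page per
#' projection, step-by-pixel), reference frames likewise, with protocol and
#' geometry recorded in the JSON sidecars.
#'
#' @param scan a `stepping_scan`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "stepping_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  na <- dim(scan$sample_frames)[1]
  sp <- file.path(dir, "sample_frames.tif")
  .write_float_tiff(lapply(seq_len(na), function(a) scan$sample_frames[a, , ]),
                    sp, extra = list(layout = "projection pages, step x pixel",
                                     protocol = unclass(scan$protocol)))
  nb <- dim(scan$reference_frames)[1]
  rp <- file.path(dir, "reference_frames.tif")
  pages <- list()
  for (b in seq_len(nb)) {
    for (rrep in seq_len(dim(scan$reference_frames)[2])) {
      pages[[length(pages) + 1L]] <- scan$reference_frames[b, rrep, , ]
    }
  }
  .write_float_tiff(pages, rp,
                    extra = list(layout = "block*repeat pages, step x pixel",
                                 block_projections = scan$block_projections))
  invisible(c(sp, rp))
}
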