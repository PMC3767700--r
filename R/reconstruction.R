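# Frequency-domain filtering of sinogram rows on zero-padded projections.
# Padding to >= 2x the next power of two suppresses circular-convolution
# wraparound. The band-limited filters are applied through the DFT of their
# discrete spatial kernels (sampling the ideal responses |f|, respectively
# sgn(f)/(2*pi*i) for derivative sinograms, directly on the DFT frequency
# grid biases the low frequencies and shades reconstructed values down by a
# few percent):
#   ramp:    h[0] = 1/(4 d^2),  h[n] = -1/(pi n d)^2 (odd n),  0 (even n)
#   hilbert: h[n] = 1/(pi^2 n d) (odd n),  0 (even n and 0)
# with d the detector pitch. Both kernels have exactly zero DC response.
.filter_sinogram <- function(sino, pitch_m, kernel = c("ramlak", "hilbert")) {
  kernel <- match.arg(kernel)
  nd <- ncol(sino)
  np <- 2^ceiling(log2(2 * nd))
  idx <- c(seq(0, np / 2), seq(-np / 2 + 1, -1))  # wrapped kernel offsets
  h <- numeric(np)
  odd <- idx %% 2 != 0
  if (kernel == "ramlak") {
    h[idx == 0] <- 1 / (4 * pitch_m^2)
    h[odd] <- -1 / (pi * idx[odd] * pitch_m)^2
  } else {
    h[odd] <- 1 / (pi^2 * idx[odd] * pitch_m)
  }
  H <- stats::fft(h)
  padded <- matrix(0, nrow(sino), np)
  padded[, seq_len(nd)] <- sino
  ft <- t(stats::mvfft(t(padded)))
  ft <- sweep(ft, 2, H, `*`)
  out <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / np * pitch_m
  out[, seq_len(nd), drop = FALSE]
}

.check_fbp_inputs <- function(sino, angles) {
  if (!all(is.finite(sino))) {
    .stopf("sinogram contains non-finite values; fill masked pixels first")
  }
  if (length(angles) < 2) .stopf("at least 2 projection angles are required")
  span <- max(angles) - min(angles)
  if (span < pi - pi / length(angles) - 1e-9) {
    .stopf("projection angles must span at least 180 degrees")
  }
}

#' Filtered backprojection with a Ram-Lak filter
#'
#' Standard FBP for integral sinograms: each projection is ramp-filtered
#' (|f|, no apodization window) in the frequency domain on zero-padded rows,
#' then backprojected with linear interpolation. Projections covering 360
#' degrees are used with uniform weights (the pi/n_angles quadrature counts
#' each opposite-ray pair once).
#'
#' @param sinogram matrix (angle x detector), e.g. -log(T) line integrals.
#' @param angles projection angles in radians (uniform, spanning >= 180
#'   degrees).
#' @param pitch_um detector pitch in micrometers.
#' @param n output grid size in pixels (default: detector size).
#' @return reconstructed square map; for -log(T) input the units are 1/m.
#' @export
fbp_ramlak <- function(sinogram, angles, pitch_um, n = ncol(sinogram)) {
  .check_fbp_inputs(sinogram, angles)
  .check_number(pitch_um, "pitch_um")
  q <- .filter_sinogram(sinogram, pitch_um * 1e-6, "ramlak")
  bp <- cpp_backproject(q, as.numeric(angles), as.integer(n), pitch_um * 1e-6)
  (pi / length(angles)) * bp
}

#' Filtered backprojection of differential phase with the imaginary Hilbert
#' filter
#'
#' Reconstructs a refractive-index-decrement (delta) map directly from a
#' differential-phase sinogram. The sinogram is first rescaled by
#' `p2 / (2*pi*d_s)` (the inverse of the interferometer's angular
#' sensitivity) to the transverse derivative of the delta line integrals,
#' then filtered with the imaginary Hilbert kernel `sgn(f)/(2*pi*i)` -- the
#' ramp filter divided by the derivative response -- and backprojected. The
#' derivative kills the DC component, so the map's offset is anchored
#' afterwards: the configured background region is forced to average to
#' `background_delta` (default: corner patches outside the vessel, anchored
#' to the background material's delta).
#'
#' @param phi_sinogram differential-phase sinogram in radians (angle x
#'   detector), unwrapped.
#' @param angles projection angles in radians.
#' @param geometry a [geometry_config()] supplying d_s and p2.
#' @param pitch_um detector pitch in micrometers.
#' @param n output grid size.
#' @param background_delta delta value the anchoring region is set to.
#' @param anchor logical n x n mask of anchoring pixels, or `"corners"`
#'   (default: four corner patches of n/8 x n/8 pixels).
#' @return reconstructed delta map (dimensionless).
#' @export
fbp_hilbert <- function(phi_sinogram, angles, geometry, pitch_um,
                        n = ncol(phi_sinogram), background_delta = 0,
                        anchor = "corners") {
  .check_fbp_inputs(phi_sinogram, angles)
  if (!inherits(geometry, "geometry_config")) {
    .stopf("fbp_hilbert requires a geometry_config (for d_s and p2)")
  }
  .check_number(pitch_um, "pitch_um")
  d_s <- geometry$phase_to_analyzer_cm * 1e-2
  p2 <- geometry$p2_um * 1e-6
  g <- phi_sinogram * p2 / (2 * pi * d_s)
  q <- .filter_sinogram(g, pitch_um * 1e-6, "hilbert")
  bp <- cpp_backproject(q, as.numeric(angles), as.integer(n), pitch_um * 1e-6)
  map <- (pi / length(angles)) * bp
  amask <- .anchor_mask(anchor, n)
  map - mean(map[amask]) + background_delta
}

.anchor_mask <- function(anchor, n) {
  if (is.matrix(anchor)) {
    stopifnot(is.logical(anchor), all(dim(anchor) == c(n, n)), any(anchor))
    return(anchor)
  }
  if (!identical(anchor, "corners")) {
    .stopf("anchor must be \"corners\" or a logical mask")
  }
  k <- max(4L, n %/% 8L)
  m <- matrix(FALSE, n, n)
  idx <- c(seq_len(k), n - seq_len(k) + 1L)
  m[idx, idx] <- TRUE
  m
}

# fill masked (NA) sinogram pixels by linear interpolation along the detector
.fill_masked <- function(sino, mask, fill) {
  if (all(mask)) return(sino)
  for (a in seq_len(nrow(sino))) {
    bad <- !mask[a, ]
    if (!any(bad)) next
    good <- which(!bad)
    if (length(good) < 2) {
      sino[a, bad] <- fill
    } else {
      sino[a, bad] <- stats::approx(good, sino[a, good], xout = which(bad),
                                    rule = 2)$y
    }
  }
  sino
}

#' Reconstruct both contrast channels
#'
#' Ram-Lak FBP of -log(T) to an attenuation (mu) map and imaginary-Hilbert
#' FBP of the unwrapped differential phase to a delta map, on the same grid.
#' Masked sinogram pixels are filled by interpolation along the detector
#' before filtering.
#'
#' @param sinos a `contrast_sinograms` from [retrieve_scan()].
#' @param pitch_um detector pitch in micrometers.
#' @param geometry a [geometry_config()]; defaults to the one carried by
#'   `sinos`.
#' @param angles projection angles; default those carried by `sinos`.
#' @param n output grid size.
#' @param background_delta anchoring value for the delta map.
#' @param anchor see [fbp_hilbert()].
#' @param provenance optional list recorded in the result.
#' @return an object of class `recon_pair` with `mu_map` (1/m), `delta_map`,
#'   `pixel_pitch_um`, `angles_used`, `provenance`.
#' @export
reconstruct_pair <- function(sinos, pitch_um, geometry = sinos$geometry,
                             angles = sinos$angles,
                             n = ncol(sinos$transmission),
                             background_delta = 0, anchor = "corners",
                             provenance = list()) {
  stopifnot(inherits(sinos, "contrast_sinograms"))
  Ts <- .fill_masked(sinos$transmission, sinos$mask, fill = 1)
  Ts[Ts <= 0] <- .Machine$double.eps
  phis <- .fill_masked(sinos$dphase, sinos$mask, fill = 0)
  phis <- unwrap_dphase(phis)
  mu_map <- fbp_ramlak(-log(Ts), angles, pitch_um, n)
  delta_map <- fbp_hilbert(phis, angles, geometry, pitch_um, n,
                           background_delta = background_delta,
                           anchor = anchor)
  structure(list(mu_map = mu_map, delta_map = delta_map,
                 pixel_pitch_um = pitch_um, angles_used = length(angles),
                 provenance = provenance),
            class = "recon_pair")
}

#' @export
print.recon_pair <- function(x, ...) {
  cat(sprintf(
    "Reconstruction pair: %dx%d px at %.2f um, %d angles\n  mu: [%.3g, %.3g] 1/m; delta: [%.3g, %.3g]\n",
    nrow(x$mu_map), ncol(x$mu_map), x$pixel_pitch_um, x$angles_used,
    min(x$mu_map), max(x$mu_map), min(x$delta_map), max(x$delta_map)))
  invisible(x)
}

#' Write a reconstruction pair to disk
#'
#' Two single-page float TIFFs plus a JSON provenance sidecar.
#'
#' @param recon a `recon_pair`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_recon_pair <- function(recon, dir) {
  stopifnot(inherits(recon, "recon_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mp <- file.path(dir, "mu_map.tif")
  dp <- file.path(dir, "delta_map.tif")
  .write_float_tiff(recon$mu_map, mp,
                    extra = list(channel = "mu (1/m)",
                                 pixel_pitch_um = recon$pixel_pitch_um))
  .write_float_tiff(recon$delta_map, dp,
                    extra = list(channel = "delta",
                                 pixel_pitch_um = recon$pixel_pitch_um))
  jsonlite::write_json(c(list(angles_used = recon$angles_used,
                              pixel_pitch_um = recon$pixel_pitch_um),
                         recon$provenance),
                       file.path(dir, "recon_provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(mp, dp))
}
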