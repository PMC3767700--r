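#' Fourier analysis of a phase-stepping curve
#'
#' Discrete Fourier analysis at harmonic 1 of K evenly spaced samples over
#' one grating period: `a0` is the curve mean, `a1 = (2/K)*|Z|` the
#' first-harmonic amplitude and `ph1 = Arg(Z)` the first-harmonic phase,
#' with `Z = sum_k I_k exp(-2*pi*i*k/K)`. Exact for single-harmonic curves.
#' Curves with (numerically) zero modulation are flagged rather than
#' rejected.
#'
#' @param frames numeric vector of length K, or a K x M matrix of M curves
#'   in columns.
#' @return list with `a0`, `a1`, `ph1`, `flagged` (each length M).
#' @examples
#' fit_stepping_curve(c(130, 100, 70, 100))  # a0 100, a1 30, ph1 0
#' @export
fit_stepping_curve <- function(frames) {
  if (is.vector(frames)) frames <- matrix(frames, ncol = 1L)
  K <- nrow(frames)
  if (K < 3) .stopf("at least 3 phase steps are required (got %d)", K)
  if (any(!is.finite(frames)) || any(frames < 0)) {
    .stopf("stepping frames must be finite and non-negative")
  }
  w <- exp(-2i * pi * (seq_len(K) - 1) / K)
  Z <- as.vector(crossprod(frames, w))
  a0 <- colMeans(frames)
  a1 <- (2 / K) * Mod(Z)
  ph1 <- Arg(Z)
  flagged <- a1 <= pmax(a0, 1) * sqrt(.Machine$double.eps)
  list(a0 = a0, a1 = a1, ph1 = ph1, flagged = flagged)
}

# fit every (angle, pixel) curve of an (angle x step x pixel) array;
# returns angle x pixel matrices
.fit_frames_array <- function(frames) {
  na <- dim(frames)[1]; K <- dim(frames)[2]; nd <- dim(frames)[3]
  w <- exp(-2i * pi * (seq_len(K) - 1) / K)
  Z <- matrix(0 + 0i, na, nd)
  a0 <- matrix(0, na, nd)
  for (k in seq_len(K)) {
    Z <- Z + frames[, k, ] * w[k]
    a0 <- a0 + frames[, k, ]
  }
  a0 <- a0 / K
  list(a0 = a0, a1 = (2 / K) * Mod(Z), ph1 = Arg(Z), Z = Z,
       flagged = (2 / K) * Mod(Z) <= pmax(a0, 1) * sqrt(.Machine$double.eps))
}

#' Flat-field correction of stepping-curve fits
#'
#' Normalizes per-projection sample fits by reference (flat) fits:
#' `T = a0_s / a0_r`, `phi = wrap(ph1_r - ph1_s)` (sign chosen so that the
#' retrieved phi equals the phi fed to [simulate_stepping()]), and
#' `D = (a1_s/a0_s) / (a1_r/a0_r)`. Pixels whose reference visibility
#' `a1_r/a0_r` falls below `visibility_floor`, or whose reference mean is
#' zero, are masked rather than raising an error.
#'
#' @param sample_fits list of `a0`, `a1`, `ph1` matrices (angle x pixel).
#' @param reference_fits same structure, one row per reference block.
#' @param assignment integer vector mapping each projection to a reference
#'   block (nearest preceding block).
#' @param visibility_floor minimum usable reference visibility (default
#'   0.005, i.e. 0.5% of a0_r).
#' @return an object of class `contrast_sinograms` with `transmission`,
#'   `dphase` (wrapped to (-pi, pi\]), `darkfield` and logical `mask`
#'   (`TRUE` = usable pixel).
#' @export
flat_field <- function(sample_fits, reference_fits, assignment,
                       visibility_floor = 0.005) {
  na <- nrow(sample_fits$a0)
  stopifnot(length(assignment) == na)
  a0r <- reference_fits$a0[assignment, , drop = FALSE]
  a1r <- reference_fits$a1[assignment, , drop = FALSE]
  ph1r <- reference_fits$ph1[assignment, , drop = FALSE]

  vis_r <- ifelse(a0r > 0, a1r / a0r, 0)
  mask <- a0r > 0 & vis_r >= visibility_floor
  safe_a0r <- ifelse(a0r > 0, a0r, 1)
  safe_a1r <- ifelse(a1r > 0, a1r, 1)

  transmission <- sample_fits$a0 / safe_a0r
  dphase <- wrap_phase(ph1r - sample_fits$ph1)
  vis_s <- ifelse(sample_fits$a0 > 0, sample_fits$a1 / sample_fits$a0, 0)
  darkfield <- vis_s / ifelse(vis_r > 0, vis_r, 1)
  transmission[!mask] <- NA_real_
  dphase[!mask] <- NA_real_
  darkfield[!mask] <- NA_real_

  structure(list(transmission = transmission, dphase = dphase,
                 darkfield = darkfield, mask = mask),
            class = "contrast_sinograms")
}

#' Retrieve the three contrast sinograms from a stepping scan
#'
#' Fits every sample and reference stepping curve ([fit_stepping_curve()]),
#' averages the reference fits within each block (complex average of the
#' first harmonic), assigns each projection its nearest preceding reference
#' block, and flat-fields.
#'
#' @param scan a `stepping_scan` from [simulate_stepping()].
#' @param visibility_floor see [flat_field()].
#' @return a `contrast_sinograms` object; carries `angles`, `geometry` and
#'   the scan pixel pitch when available.
#' @export
retrieve_scan <- function(scan, visibility_floor = 0.005) {
  stopifnot(inherits(scan, "stepping_scan"))
  sfit <- .fit_frames_array(scan$sample_frames)

  rb <- dim(scan$reference_frames)
  nb <- rb[1]; nrep <- rb[2]; K <- rb[3]; nd <- rb[4]
  a0 <- matrix(0, nb, nd); Z <- matrix(0 + 0i, nb, nd)
  for (b in seq_len(nb)) {
    block <- array(scan$reference_frames[b, , , ], dim = c(nrep, K, nd))
    # average fits over the repeats within the block
    fit <- .fit_frames_array(block)           # nrep x nd
    a0[b, ] <- colMeans(fit$a0)
    Z[b, ] <- colMeans(fit$Z)
  }
  rfit <- list(a0 = a0, a1 = (2 / K) * Mod(Z), ph1 = Arg(Z))

  na <- dim(scan$sample_frames)[1]
  assignment <- findInterval(seq_len(na), scan$block_projections)
  out <- flat_field(list(a0 = sfit$a0, a1 = sfit$a1, ph1 = sfit$ph1),
                    rfit, assignment, visibility_floor)
  out$angles <- scan$angles
  out$geometry <- scan$geometry
  out
}

#' One-dimensional phase unwrapping along the detector
#'
#' Forces successive differences along each detector row into (-pi, pi\] and
#' reintegrates, removing 2*pi jumps. Applied per projection angle.
#'
#' @param phi matrix (angle x detector) of wrapped phases, or a numeric
#'   vector (single profile).
#' @return unwrapped phases, same shape.
#' @export
unwrap_dphase <- function(phi) {
  unwrap1 <- function(x) {
    ok <- is.finite(x)
    if (sum(ok) < 2) return(x)
    # unwrap the finite samples in place, leaving NAs where they were
    v <- x[ok]
    d <- wrap_phase(diff(v))
    x[ok] <- v[1] + c(0, cumsum(d))
    x
  }
  if (is.vector(phi)) return(unwrap1(phi))
  t(apply(phi, 1, unwrap1))
}

#' @export
print.contrast_sinograms <- function(x, ...) {
  cat(sprintf(
    "Contrast sinograms: %d angles x %d pixels (%.1f%% masked)\n",
    nrow(x$transmission), ncol(x$transmission), 100 * mean(!x$mask)))
  invisible(x)
}

#' Write contrast sinograms to disk
#'
#' @param sinos a `contrast_sinograms`.
#' @param dir output directory.
#' @return invisibly, the path written.
#' @export
write_sinograms <- function(sinos, dir) {
  stopifnot(inherits(sinos, "contrast_sinograms"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(dir, "sinograms.tif")
  tr <- sinos$transmission; dp <- sinos$dphase; df <- sinos$darkfield
  tr[!sinos$mask] <- 1; dp[!sinos$mask] <- 0; df[!sinos$mask] <- 1
  .write_float_tiff(list(tr, dp, df, sinos$mask + 0), p,
                    extra = list(pages_named = c("transmission", "dphase",
                                                 "darkfield", "mask")))
  invisible(p)
}
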