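#' ROI signal-to-noise ratio between a tissue and a background region
#'
#' `snr = |mean_tissue - mean_background| / sd_background` by default; a
#' pooled-SD alternative `|dm| / sqrt((sd_t^2 + sd_b^2)/2)` is available.
#' Both use only ROI means and standard deviations.
#'
#' @param image numeric matrix (a reconstructed channel).
#' @param tissue_roi,background_roi disjoint logical masks with at least 10
#'   pixels each.
#' @param noise `"background"` (default) or `"pooled"`.
#' @return list with `snr`, `mean_tissue`, `mean_background`, `sd_tissue`,
#'   `sd_background`.
#' @export
roi_snr <- function(image, tissue_roi, background_roi,
                    noise = c("background", "pooled")) {
  noise <- match.arg(noise)
  stopifnot(is.logical(tissue_roi), is.logical(background_roi),
            all(dim(tissue_roi) == dim(image)),
            all(dim(background_roi) == dim(image)))
  if (any(tissue_roi & background_roi)) .stopf("ROIs must be disjoint")
  if (sum(tissue_roi) < 10 || sum(background_roi) < 10) {
    .stopf("each ROI needs at least 10 pixels")
  }
  mt <- mean(image[tissue_roi]); mb <- mean(image[background_roi])
  st <- stats::sd(image[tissue_roi]); sb <- stats::sd(image[background_roi])
  denom <- switch(noise, background = sb, pooled = sqrt((st^2 + sb^2) / 2))
  if (denom == 0) .stopf("background standard deviation is zero")
  list(snr = abs(mt - mb) / denom, mean_tissue = mt, mean_background = mb,
       sd_tissue = st, sd_background = sb)
}

#' Extract an eroded ROI mask from a phantom label map
#'
#' The region's pixels eroded by a disc to avoid partial-volume edges, with
#' an optional margin excluding the outermost image frame (reconstruction
#' edge artifacts).
#'
#' @param phantom a `vessel_phantom`.
#' @param region region name (see [REGION_IDS]).
#' @param erode_px erosion radius in pixels (0 disables).
#' @param margin_px frame width excluded at the image border.
#' @return logical mask.
#' @export
roi_from_phantom <- function(phantom, region, erode_px = 2L, margin_px = 6L) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  id <- REGION_IDS[[match.arg(region, names(REGION_IDS))]]
  mask <- phantom$label_map == id
  if (erode_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(erode_px) + 1L, "disc")
    mask <- EBImage::erode(mask + 0, brush) > 0.5
  }
  if (margin_px > 0) {
    n <- nrow(mask)
    idx <- c(seq_len(margin_px), n - seq_len(margin_px) + 1L)
    mask[idx, ] <- FALSE
    mask[, idx] <- FALSE
  }
  if (!any(mask)) .stopf("ROI for region '%s' is empty after erosion", region)
  mask
}

#' Background-fluid annulus around the vessel
#'
#' A ring of background pixels immediately outside the outermost vessel
#' boundary: the natural "surrounding fluid" region, used both as the SNR
#' background ROI and as the offset anchor for the delta map (differential
#' data carry no very-low-frequency information, so anchoring adjacent to
#' the specimen is less biased than anchoring at the far corners).
#'
#' @param phantom a `vessel_phantom`.
#' @param pad_px gap between the vessel's outermost boundary and the ring.
#' @param width_px radial width of the ring.
#' @return logical mask.
#' @export
roi_background_annulus <- function(phantom, pad_px = 3L, width_px = 8L) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  spec <- phantom$spec
  n <- spec$grid_size
  psi_chk <- seq(-pi, pi, length.out = 721L)
  rmax <- max(.eval_boundaries(phantom$boundaries, psi_chk)$adventitia)
  co <- .grid_coords(n, spec$pixel_pitch_um)
  r <- sqrt((co$X - spec$center_um[1])^2 + (co$Y - spec$center_um[2])^2)
  inner <- rmax + pad_px * spec$pixel_pitch_um
  outer <- inner + width_px * spec$pixel_pitch_um
  # stay clear of the graded tube rim (centered on the grid)
  r_grid <- sqrt(co$X^2 + co$Y^2)
  rim_start <- spec$bath_radius_um -
    (spec$bath_taper_px / 2 + 1) * spec$pixel_pitch_um
  mask <- r > inner & r <= outer & r_grid < rim_start &
    phantom$label_map == REGION_IDS[["background"]]
  if (!any(mask)) .stopf("background annulus is empty; widen the field")
  mask
}

#' Mask-based area morphometry
#'
#' Areas as pixel counts times pitch^2, with the derived `wall`
#' (intima + media) and `total_vessel` (lumen + wall) rows of vessel-wall
#' morphometry recomputed from the component masks.
#'
#' @param masks named list of disjoint logical masks (expects at least
#'   `lumen`, `intima`, `media` for the derived rows).
#' @param pitch_um pixel pitch in micrometers.
#' @param reader reader identifier recorded in the table.
#' @param modality modality tag (`"recon"` or `"ground_truth"`).
#' @return data frame with `region`, `area_mm2`, `reader`, `modality`.
#' @export
measure_areas <- function(masks, pitch_um, reader = "reader1",
                          modality = "recon") {
  stopifnot(is.list(masks), length(masks) >= 1, !is.null(names(masks)))
  acc <- masks[[1]] * 0
  for (m in masks) {
    stopifnot(is.logical(m))
    acc <- acc + m
  }
  if (any(acc > 1)) .stopf("region masks overlap")
  px_mm2 <- (pitch_um * 1e-3)^2
  out <- data.frame(region = names(masks),
                    area_mm2 = vapply(masks, sum, numeric(1)) * px_mm2,
                    stringsAsFactors = FALSE)
  if (all(c("lumen", "intima", "media") %in% out$region)) {
    wall_regions <- intersect(
      c("intima", "media", "lipid_core", "calcification", "fibrous_cap"),
      out$region)
    wall <- sum(out$area_mm2[out$region %in% wall_regions])
    lumen <- out$area_mm2[out$region == "lumen"]
    out <- rbind(out, data.frame(region = c("wall", "total_vessel"),
                                 area_mm2 = c(wall, lumen + wall)))
  }
  out$reader <- reader
  out$modality <- modality
  rownames(out) <- NULL
  out
}

#' Intraclass correlation coefficient, two-way random, absolute agreement,
#' single measure
#'
#' ICC(A,1) from the two-way ANOVA mean squares of a targets-by-raters
#' table: `(MSR - MSE) / (MSR + (k-1)*MSE + (k/n)*(MSC - MSE))` with n
#' targets and k = 2 raters.
#'
#' @param reader1,reader2 paired measurements (length n >= 3).
#' @return ICC in \[-1, 1\].
#' @export
icc_absolute_agreement <- function(reader1, reader2) {
  stopifnot(length(reader1) == length(reader2))
  n <- length(reader1)
  if (n < 3) .stopf("at least 3 paired observations are required")
  x <- cbind(reader1, reader2)
  k <- 2
  if (stats::var(as.vector(x)) == 0) {
    .stopf("zero total variance: ICC undefined")
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Slope regression of reference areas on measured areas
#'
#' Ordinary least squares of `reference ~ measured` (predicting the
#' reference, e.g. histology-like ground truth, from the image-based
#' measurement), with a large-sample 95% confidence interval for the slope.
#'
#' @param measured,reference numeric vectors (n >= 3).
#' @return list with `slope`, `ci` (length 2), `se`, `intercept`, `n`.
#' @export
slope_vs_reference <- function(measured, reference) {
  stopifnot(length(measured) == length(reference))
  if (length(measured) < 3) .stopf("at least 3 observations are required")
  if (stats::var(measured) == 0) {
    .stopf("zero variance in measured areas: slope undefined")
  }
  fit <- stats::lm(reference ~ measured)
  est <- unname(coef(fit)["measured"])
  n <- length(measured)
  # standard error computed directly (summary.lm warns on perfect fits)
  sxx <- sum((measured - mean(measured))^2)
  s2 <- sum(stats::residuals(fit)^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  z <- stats::qnorm(0.975)
  list(slope = est, ci = c(est - z * se, est + z * se), se = se,
       intercept = unname(coef(fit)[1]), n = n)
}

#' Simulate a human reader tracing vessel boundaries
#'
#' Emulates manual area tracing by perturbing every layer boundary of the
#' phantom: radii are scaled by `(1 + bias)` (a systematic over- or
#' under-tracing; area bias is then `(1 + bias)^2`) plus smooth random
#' angular noise of amplitude `boundary_noise_um`, and the label map is
#' re-rasterized so that the partition and the additive wall/total
#' convention are preserved by construction. Inclusion masks are kept as in
#' the ground truth. Deterministic under `seed`.
#'
#' @param phantom a `vessel_phantom`.
#' @param bias fractional radial bias (0 = unbiased; 0.1 means all traced
#'   boundaries 10% further out).
#' @param boundary_noise_um amplitude of the random boundary error in
#'   micrometers.
#' @param seed integer seed.
#' @param reader reader identifier for the output table.
#' @return an area table as from [measure_areas()], with the perturbed masks
#'   in attribute `"masks"`.
#' @export
reader_simulation <- function(phantom, bias = 0, boundary_noise_um = 0,
                              seed = 1L, reader = "reader1") {
  stopifnot(inherits(phantom, "vessel_phantom"))
  spec <- phantom$spec
  n <- spec$grid_size
  noise <- withr_seed(seed, {
    lapply(1:4, function(i) .make_jitter(boundary_noise_um, 4L))
  })

  co <- .grid_coords(n, spec$pixel_pitch_um)
  dx <- co$X - spec$center_um[1]
  dy <- co$Y - spec$center_um[2]
  r <- sqrt(dx^2 + dy^2)
  psi <- as.vector(atan2(dy, dx))
  noise_v <- lapply(noise, function(j) matrix(.jitter_eval(j, psi), n, n))
  radii <- .eval_boundaries(phantom$boundaries, psi, scale = 1 + bias,
                            noise = noise_v)
  radii <- lapply(radii, function(v) matrix(v, n, n))
  lab <- .labels_from_radii(r, radii)
  for (im in phantom$inclusion_masks) {
    lab[im$mask & lab != REGION_IDS[["background"]] &
          lab != REGION_IDS[["lumen"]]] <- REGION_IDS[[im$region]]
  }
  keep <- names(REGION_IDS)[REGION_IDS %in% sort(unique(as.vector(lab)))]
  keep <- setdiff(keep, c("background", "air"))
  masks <- lapply(keep, function(rg) lab == REGION_IDS[[rg]])
  names(masks) <- keep
  out <- measure_areas(masks, spec$pixel_pitch_um, reader = reader,
                       modality = "recon")
  attr(out, "masks") <- masks
  out
}
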