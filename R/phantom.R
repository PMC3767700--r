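#' Region identifiers used in phantom label maps
#'
#' Fixed mapping: 0 background (bath fluid), 1 lumen fluid, 2 tunica intima,
#' 3 tunica media, 4 tunica adventitia, 5 lipid/necrotic core,
#' 6 calcification, 7 fibrous cap, 8 air outside the specimen tube.
#'
#' @export
REGION_IDS <- c(background = 0L, lumen = 1L, intima = 2L, media = 3L,
                adventitia = 4L, lipid_core = 5L, calcification = 6L,
                fibrous_cap = 7L, air = 8L)

#' Specify a layered vessel cross-section phantom
#'
#' Describes an elliptical lumen surrounded by strictly nested intima, media
#' and adventitia rings, with optional plaque inclusions (disc-shaped
#' calcifications, crescent-shaped lipid cores and fibrous caps) embedded in
#' the wall, and optional smooth radial boundary irregularity.
#'
#' @param grid_size image size in pixels (square grid).
#' @param pixel_pitch_um pixel pitch in micrometers.
#' @param center_um vessel center (x, y) in micrometers relative to the grid
#'   center.
#' @param lumen_semi_axes_um ellipse semi-axes (a, b) of the lumen in
#'   micrometers.
#' @param layer_thickness_um named numeric vector with positive entries
#'   `intima`, `media`, `adventitia` (radial thicknesses in micrometers).
#' @param inclusions list of inclusion specs; each a list with `shape`
#'   (`"disc"` or `"crescent"`), `region` (`"lipid_core"`, `"calcification"`
#'   or `"fibrous_cap"`), `material` (defaults to `region`), `layer`
#'   (`"intima"`, `"media"` or `"adventitia"`), `theta_center` (radians) and,
#'   for discs, `frac` (radial position within the layer, 0-1) and
#'   `radius_um`; for crescents, `theta_width` (radians) and `frac` (length-2
#'   radial fraction range within the layer).
#' @param background_material,lumen_material material names.
#' @param bath_radius_um radius of the fluid-filled specimen tube, centered
#'   on the grid; pixels outside it are air. `NULL` (default) uses 45% of
#'   the field width, keeping the tube edge well inside the field of view so
#'   projections are not truncated.
#' @param bath_taper_px width (pixels) over which the optical constants
#'   grade from bath fluid to air at the tube rim, emulating the tube wall
#'   and system blur. A sharp rim would step the differential phase by more
#'   than pi between adjacent detector pixels, which no one-dimensional
#'   unwrapper can undo; the taper keeps per-pixel phase increments
#'   unwrappable. Labels are not graded (the rim stays a sharp
#'   background/air label boundary).
#' @param jitter_um amplitude of smooth radial boundary irregularity in
#'   micrometers (0 disables it).
#' @param jitter_modes number of angular Fourier modes in the jitter.
#' @param seed integer seed for the boundary jitter.
#' @return an object of class `vessel_spec`.
#' @export
vessel_spec <- function(grid_size = 128L, pixel_pitch_um = 5.4,
                        center_um = c(0, 0),
                        lumen_semi_axes_um = c(90, 75),
                        layer_thickness_um = c(intima = 25, media = 45,
                                               adventitia = 30),
                        inclusions = list(),
                        background_material = "water",
                        lumen_material = "water",
                        bath_radius_um = NULL, bath_taper_px = 4,
                        jitter_um = 0, jitter_modes = 3L, seed = 1L) {
  .check_number(pixel_pitch_um, "pixel_pitch_um")
  stopifnot(grid_size >= 16, length(lumen_semi_axes_um) == 2,
            all(lumen_semi_axes_um > 0))
  need <- c("intima", "media", "adventitia")
  if (!all(need %in% names(layer_thickness_um)) ||
      any(layer_thickness_um[need] <= 0)) {
    .stopf("layer_thickness_um needs positive entries intima, media, adventitia")
  }
  if (jitter_um < 0) .stopf("jitter_um must be >= 0")
  if (is.null(bath_radius_um)) {
    bath_radius_um <- 0.45 * grid_size * pixel_pitch_um
  }
  .check_number(bath_radius_um, "bath_radius_um")
  if (bath_taper_px < 0) .stopf("bath_taper_px must be >= 0")
  structure(list(grid_size = as.integer(grid_size),
                 pixel_pitch_um = pixel_pitch_um,
                 center_um = center_um,
                 lumen_semi_axes_um = lumen_semi_axes_um,
                 layer_thickness_um = layer_thickness_um[need],
                 inclusions = inclusions,
                 background_material = background_material,
                 lumen_material = lumen_material,
                 bath_radius_um = bath_radius_um,
                 bath_taper_px = bath_taper_px,
                 jitter_um = jitter_um,
                 jitter_modes = as.integer(jitter_modes),
                 seed = as.integer(seed)),
            class = "vessel_spec")
}

# polar radius of an ellipse about its own center
.ellipse_radius <- function(a, b, psi) {
  a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
}

# smooth periodic jitter: sum of cosine modes, scaled to max amplitude
.make_jitter <- function(amplitude_um, modes) {
  if (amplitude_um <= 0 || modes < 1) return(NULL)
  k <- 1L + seq_len(modes)              # modes 2..modes+1 (no net dilation)
  a <- stats::runif(length(k), 0.3, 1)
  ph <- stats::runif(length(k), 0, 2 * pi)
  # normalize so the realized max |jitter| equals amplitude_um
  psi <- seq(0, 2 * pi, length.out = 721L)
  raw <- colSums(a * cos(outer(k, psi) + ph))
  list(k = k, a = a * amplitude_um / max(abs(raw)), phase = ph)
}

.jitter_eval <- function(jit, psi) {
  if (is.null(jit)) return(0)
  colSums(jit$a * cos(outer(jit$k, psi) + jit$phase))
}

# Evaluate the four cumulative boundary radii at angles psi.
# scale/noise implement reader-style perturbation r -> r*(1+bias)+noise.
.eval_boundaries <- function(bnd, psi, scale = 1, noise = NULL) {
  r_lum <- .ellipse_radius(bnd$a, bnd$b, psi) + .jitter_eval(bnd$jit[[1]], psi)
  r_int <- r_lum + bnd$thickness["intima"] + .jitter_eval(bnd$jit[[2]], psi)
  r_med <- r_int + bnd$thickness["media"] + .jitter_eval(bnd$jit[[3]], psi)
  r_adv <- r_med + bnd$thickness["adventitia"] + .jitter_eval(bnd$jit[[4]], psi)
  out <- list(lumen = r_lum, intima = r_int, media = r_med, adventitia = r_adv)
  if (scale != 1 || !is.null(noise)) {
    for (i in seq_along(out)) {
      out[[i]] <- out[[i]] * scale +
        (if (is.null(noise)) 0 else noise[[i]])
    }
  }
  out
}

# pixel-center coordinate matrices (um, relative to grid center);
# first index along +x, second along +y (shared with the C++ projector)
.grid_coords <- function(n, pitch_um) {
  ax <- (seq_len(n) - 1 - (n - 1) / 2) * pitch_um
  list(X = matrix(ax, n, n), Y = matrix(ax, n, n, byrow = TRUE))
}

.layer_bounds <- function(radii, layer) {
  switch(layer,
         intima = list(inner = radii$lumen, outer = radii$intima),
         media = list(inner = radii$intima, outer = radii$media),
         adventitia = list(inner = radii$media, outer = radii$adventitia),
         .stopf("unknown layer '%s'", layer))
}

# label matrix from boundary radii evaluated per pixel
.labels_from_radii <- function(r, radii) {
  lab <- matrix(REGION_IDS[["background"]], nrow(r), ncol(r))
  lab[r <= radii$adventitia] <- REGION_IDS[["adventitia"]]
  lab[r <= radii$media] <- REGION_IDS[["media"]]
  lab[r <= radii$intima] <- REGION_IDS[["intima"]]
  lab[r <= radii$lumen] <- REGION_IDS[["lumen"]]
  lab
}

.inclusion_mask <- function(inc, co, r, psi, radii, center_um) {
  shape <- match.arg(inc$shape, c("disc", "crescent"))
  lb <- .layer_bounds(radii, inc$layer)
  if (shape == "disc") {
    stopifnot(!is.null(inc$theta_center), !is.null(inc$frac),
              !is.null(inc$radius_um))
    if (inc$frac < 0 || inc$frac > 1) .stopf("disc frac must lie in [0, 1]")
    # center on the layer surface at theta_center, at radial fraction frac
    rc <- attr(radii, "eval")(inc$theta_center)
    lbc <- .layer_bounds(rc, inc$layer)
    r0 <- lbc$inner + inc$frac * (lbc$outer - lbc$inner)
    x0 <- center_um[1] + r0 * cos(inc$theta_center)
    y0 <- center_um[2] + r0 * sin(inc$theta_center)
    (co$X - x0)^2 + (co$Y - y0)^2 <= inc$radius_um^2
  } else {
    stopifnot(!is.null(inc$theta_center), !is.null(inc$theta_width),
              length(inc$frac) == 2)
    f <- sort(inc$frac)
    if (f[1] < 0 || f[2] > 1) .stopf("crescent frac range must lie in [0, 1]")
    dang <- abs(wrap_phase(psi - inc$theta_center))
    rin <- lb$inner + f[1] * (lb$outer - lb$inner)
    rout <- lb$inner + f[2] * (lb$outer - lb$inner)
    dang <= inc$theta_width / 2 & r >= rin & r <= rout
  }
}

#' Build a labelled vessel phantom
#'
#' Rasterizes a [vessel_spec()] to a per-pixel label map and paired
#' refractive-index decrement (delta) and attenuation (mu) maps at the given
#' energy, with a ground-truth area table (label counts times pitch^2).
#' Boundary jitter is deterministic under the spec seed.
#'
#' @param spec a [vessel_spec()].
#' @param table a material table ([default_materials()]).
#' @param energy_kev X-ray energy at which optical constants are resolved.
#' @return an object of class `vessel_phantom` with fields `label_map`,
#'   `delta_map`, `mu_map`, `pixel_pitch_um`, `areas` (data frame),
#'   `region_materials`, `boundaries`, `inclusion_masks`, `energy_kev`,
#'   `spec`.
#' @export
build_vessel_phantom <- function(spec, table = default_materials(),
                                 energy_kev = 23) {
  stopifnot(inherits(spec, "vessel_spec"))
  n <- spec$grid_size

  jits <- withr_seed(spec$seed, {
    lapply(1:4, function(i) .make_jitter(spec$jitter_um, spec$jitter_modes))
  })
  bnd <- list(a = spec$lumen_semi_axes_um[1], b = spec$lumen_semi_axes_um[2],
              thickness = spec$layer_thickness_um, jit = jits)

  # nesting check on a fine angular grid
  psi_chk <- seq(-pi, pi, length.out = 1441L)
  rr <- .eval_boundaries(bnd, psi_chk)
  gaps <- cbind(rr$lumen, rr$intima - rr$lumen, rr$media - rr$intima,
                rr$adventitia - rr$media)
  if (any(gaps <= 0)) {
    .stopf("non-nested geometry: boundary jitter exceeds a layer thickness")
  }
  rmax <- max(rr$adventitia)
  half_field <- (n / 2) * spec$pixel_pitch_um
  if (spec$bath_radius_um > half_field) {
    .stopf("bath radius %.0f um exceeds the %.0f um half-field",
           spec$bath_radius_um, half_field)
  }
  taper_um <- spec$bath_taper_px * spec$pixel_pitch_um
  if (rmax + max(abs(spec$center_um)) >
      spec$bath_radius_um - taper_um / 2) {
    .stopf("vessel (outer radius %.0f um) does not fit the %.0f um bath tube",
           rmax, spec$bath_radius_um)
  }

  co <- .grid_coords(n, spec$pixel_pitch_um)
  dx <- co$X - spec$center_um[1]
  dy <- co$Y - spec$center_um[2]
  r <- sqrt(dx^2 + dy^2)
  psi <- atan2(dy, dx)
  radii <- .eval_boundaries(bnd, as.vector(psi))
  radii <- lapply(radii, function(v) matrix(v, n, n))
  attr(radii, "eval") <- function(p) .eval_boundaries(bnd, p)
  lab <- .labels_from_radii(r, radii)
  # air outside the specimen tube (radius about the grid center)
  r_grid <- sqrt(co$X^2 + co$Y^2)
  lab[r_grid > spec$bath_radius_um] <- REGION_IDS[["air"]]

  wall_ids <- REGION_IDS[c("intima", "media", "adventitia")]
  inc_masks <- list()
  for (inc in spec$inclusions) {
    region <- match.arg(inc$region, c("lipid_core", "calcification",
                                      "fibrous_cap"))
    mask <- .inclusion_mask(inc, co, r, psi, radii, spec$center_um)
    if (!any(mask)) .stopf("inclusion '%s' rasterizes to zero pixels", region)
    if (any(!(lab[mask] %in% c(wall_ids, REGION_IDS[c("lipid_core",
                                                      "calcification",
                                                      "fibrous_cap")])))) {
      .stopf("inclusion '%s' extends outside the vessel wall", region)
    }
    lab[mask] <- REGION_IDS[[region]]
    inc_masks[[length(inc_masks) + 1L]] <-
      list(region = region, mask = mask,
           material = if (is.null(inc$material)) region else inc$material,
           layer = inc$layer)
  }

  region_materials <- c(background = spec$background_material,
                        lumen = spec$lumen_material,
                        intima = "intima", media = "media",
                        adventitia = "adventitia", air = "air")
  for (im in inc_masks) region_materials[im$region] <- im$material

  delta_map <- matrix(0, n, n)
  mu_map <- matrix(0, n, n)
  present <- sort(unique(as.vector(lab)))
  for (id in present) {
    rname <- names(REGION_IDS)[match(id, REGION_IDS)]
    oc <- resolve_constants(region_materials[[rname]], energy_kev, table)
    sel <- lab == id
    delta_map[sel] <- oc$delta
    mu_map[sel] <- oc$mu_per_m
  }

  # graded tube rim: blend fluid -> air optical constants across the taper
  if (spec$bath_taper_px > 0) {
    oc_bg <- resolve_constants(spec$background_material, energy_kev, table)
    oc_air <- resolve_constants("air", energy_kev, table)
    w <- (r_grid - (spec$bath_radius_um - taper_um / 2)) / taper_um
    zone <- w > 0 & w < 1 &
      (lab == REGION_IDS[["background"]] | lab == REGION_IDS[["air"]])
    delta_map[zone] <- (1 - w[zone]) * oc_bg$delta + w[zone] * oc_air$delta
    mu_map[zone] <- (1 - w[zone]) * oc_bg$mu_per_m + w[zone] * oc_air$mu_per_m
  }

  px_mm2 <- (spec$pixel_pitch_um * 1e-3)^2
  counts <- table(factor(as.vector(lab), levels = REGION_IDS))
  areas <- data.frame(region_id = unname(REGION_IDS),
                      region = names(REGION_IDS),
                      material = unname(region_materials[names(REGION_IDS)]),
                      n_pixels = as.integer(counts),
                      area_mm2 = as.numeric(counts) * px_mm2,
                      stringsAsFactors = FALSE)
  areas <- areas[areas$n_pixels > 0 | areas$region_id <= 4, ]
  rownames(areas) <- NULL

  structure(list(label_map = lab, delta_map = delta_map, mu_map = mu_map,
                 pixel_pitch_um = spec$pixel_pitch_um, areas = areas,
                 region_materials = region_materials,
                 boundaries = bnd, inclusion_masks = inc_masks,
                 energy_kev = energy_kev, spec = spec),
            class = "vessel_phantom")
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Ground-truth report for a phantom
#'
#' Per-region areas (mm^2) and mean optical constants, with the derived
#' `wall` (intima + media, plus inclusions embedded in those layers, plus
#' adventitia if requested) and `total_vessel` (lumen + wall) rows following
#' the additive area convention of vessel-wall morphometry.
#'
#' @param phantom a [build_vessel_phantom()] result.
#' @param include_adventitia_in_wall logical.
#' @return data frame with columns `region`, `area_mm2`, `mean_delta`,
#'   `mean_mu`.
#' @export
phantom_to_ground_truth_report <- function(phantom,
                                           include_adventitia_in_wall = FALSE) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  lab <- phantom$label_map
  px_mm2 <- (phantom$pixel_pitch_um * 1e-3)^2
  rows <- lapply(seq_len(nrow(phantom$areas)), function(i) {
    id <- phantom$areas$region_id[i]
    sel <- lab == id
    data.frame(region = phantom$areas$region[i],
               area_mm2 = sum(sel) * px_mm2,
               mean_delta = if (any(sel)) mean(phantom$delta_map[sel]) else NA,
               mean_mu = if (any(sel)) mean(phantom$mu_map[sel]) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)

  wall_regions <- c("intima", "media")
  if (include_adventitia_in_wall) wall_regions <- c(wall_regions, "adventitia")
  for (im in phantom$inclusion_masks) {
    if (im$layer %in% c("intima", "media") ||
        (include_adventitia_in_wall && im$layer == "adventitia")) {
      wall_regions <- union(wall_regions, im$region)
    }
  }
  wall <- sum(out$area_mm2[out$region %in% wall_regions])
  lumen <- out$area_mm2[out$region == "lumen"]
  derived <- data.frame(region = c("wall", "total_vessel"),
                        area_mm2 = c(wall, lumen + wall),
                        mean_delta = NA_real_, mean_mu = NA_real_,
                        stringsAsFactors = FALSE)
  rbind(out, derived)
}

#' Write phantom maps and ground truth to disk
#'
#' Writes the label, delta and mu maps as a multi-page 32-bit float TIFF plus
#' a ground-truth CSV.
#'
#' @param phantom a `vessel_phantom`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, "phantom.tif")
  .write_float_tiff(list(phantom$label_map + 0, phantom$delta_map,
                         phantom$mu_map),
                    tif, extra = list(pages_named = c("label", "delta", "mu"),
                                      pixel_pitch_um = phantom$pixel_pitch_um))
  csvp <- file.path(dir, "phantom_ground_truth.csv")
  utils::write.csv(phantom_to_ground_truth_report(phantom), csvp,
                   row.names = FALSE)
  invisible(c(tif, csvp))
}

#' @export
print.vessel_phantom <- function(x, ...) {
  cat(sprintf("Vessel phantom: %dx%d px at %.2f um (%.2f mm field)\n",
              nrow(x$label_map), ncol(x$label_map), x$pixel_pitch_um,
              nrow(x$label_map) * x$pixel_pitch_um * 1e-3))
  print(x$areas[x$areas$n_pixels > 0, c("region", "material", "area_mm2")])
  invisible(x)
}
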