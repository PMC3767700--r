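#' Define a material
#'
#' A material is specified by its mass density and a (Z_sum, formula mass)
#' pair giving electrons per formula unit, from which the electron density
#' and the free-electron refractive-index decrement follow. The linear
#' attenuation coefficient mu is not derived from first principles; it is a
#' configured per-material constant (see [default_materials()] for the
#' bundled synthetic defaults).
#'
#' @param name material name.
#' @param mass_density_g_cm3 mass density in g/cm^3.
#' @param electrons_per_unit electrons per formula unit (sum of Z).
#' @param mass_per_unit_g_mol formula mass in g/mol.
#' @param mu_per_m optional linear attenuation coefficient in 1/m at
#'   `mu_energy_kev`.
#' @param mu_energy_kev energy at which `mu_per_m` applies (informational).
#' @return an object of class `pcct_material`.
#' @export
material <- function(name, mass_density_g_cm3, electrons_per_unit,
                     mass_per_unit_g_mol, mu_per_m = NA_real_,
                     mu_energy_kev = NA_real_) {
  .check_number(mass_density_g_cm3, "mass_density_g_cm3")
  .check_number(electrons_per_unit, "electrons_per_unit")
  .check_number(mass_per_unit_g_mol, "mass_per_unit_g_mol")
  structure(list(name = name,
                 mass_density_g_cm3 = mass_density_g_cm3,
                 electrons_per_unit = electrons_per_unit,
                 mass_per_unit_g_mol = mass_per_unit_g_mol,
                 mu_per_m = mu_per_m,
                 mu_energy_kev = mu_energy_kev),
            class = "pcct_material")
}

#' Bundled material table
#'
#' Reads the material table shipped with the package. Grating materials
#' (nickel, silicon, gold) and water use standard physical densities; the
#' soft-tissue entries (intima, media, adventitia, lipid core, fibrous cap,
#' calcification) are *synthetic defaults*: their electron densities are set
#' within a few percent of water and their mu values are bundled plausible
#' constants near 23 keV, chosen so that vessel-layer contrast is relatively
#' larger in delta than in mu, as is characteristic of soft tissue in this
#' energy range. They are simulation parameters, not measured tissue data.
#'
#' @param path optional path to a material CSV (columns `name`,
#'   `mass_density_g_cm3`, `electrons_per_unit`, `mass_per_unit_g_mol`,
#'   `mu_per_m`, `mu_energy_kev`).
#' @return an object of class `material_table` (named list of
#'   [material()] records).
#' @export
default_materials <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.csv", package = "pcct",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  mats <- lapply(seq_len(nrow(df)), function(i) {
    material(df$name[i], df$mass_density_g_cm3[i], df$electrons_per_unit[i],
             df$mass_per_unit_g_mol[i], df$mu_per_m[i], df$mu_energy_kev[i])
  })
  names(mats) <- df$name
  structure(mats, class = "material_table")
}

#' Look up a material in a table
#'
#' @param material a material name or a [material()] object.
#' @param table a `material_table`.
#' @return the [material()] record.
#' @export
get_material <- function(material, table = default_materials()) {
  if (inherits(material, "pcct_material")) return(material)
  if (!is.character(material) || length(material) != 1L) {
    .stopf("material must be a name or a pcct_material object")
  }
  if (!material %in% names(table)) {
    .stopf("unknown material '%s' (registered: %s)", material,
           paste(names(table), collapse = ", "))
  }
  table[[material]]
}

#' Electron density of a material
#'
#' rho * N_A * Z_sum / formula_mass, in electrons per m^3.
#'
#' @inheritParams get_material
#' @return electron density in 1/m^3.
#' @examples
#' electron_density("water")  # ~3.34e29
#' @export
electron_density <- function(material, table = default_materials()) {
  m <- get_material(material, table)
  # g/cm^3 -> g/m^3 is 1e6
  m$mass_density_g_cm3 * 1e6 * N_AVOGADRO *
    m$electrons_per_unit / m$mass_per_unit_g_mol
}

#' Refractive-index decrement under the free-electron model
#'
#' delta = r_e * lambda^2 * n_e / (2*pi), valid far from absorption edges;
#' energies outside 5-100 keV raise a warning (the Thomson approximation is
#' not validated there), not an error.
#'
#' @inheritParams get_material
#' @param energy_kev photon energy in keV.
#' @return dimensionless delta.
#' @examples
#' delta_free_electron("water", 23)   # ~4.36e-7
#' @export
delta_free_electron <- function(material, energy_kev,
                                table = default_materials()) {
  .check_number(energy_kev, "energy_kev")
  if (energy_kev < 5 || energy_kev > 100) {
    warning(sprintf(
      "free-electron delta not validated at %g keV (range 5-100 keV)",
      energy_kev), call. = FALSE)
  }
  lambda <- wavelength_from_energy(energy_kev)
  R_ELECTRON_M * lambda^2 * electron_density(material, table) / (2 * pi)
}

#' Resolve paired optical constants (delta, mu) at an energy
#'
#' delta always comes from the free-electron model; mu comes from the
#' material's configured `mu_per_m` (an explicit override or the bundled
#' synthetic default). A material without any mu is an error that names it.
#'
#' @inheritParams delta_free_electron
#' @param mu_override_per_m optional mu in 1/m that wins over the table value.
#' @return list with `delta`, `mu_per_m`, `energy_kev`.
#' @export
resolve_constants <- function(material, energy_kev,
                              table = default_materials(),
                              mu_override_per_m = NULL) {
  m <- get_material(material, table)
  mu <- if (!is.null(mu_override_per_m)) mu_override_per_m else m$mu_per_m
  if (is.null(mu) || is.na(mu)) {
    .stopf("material '%s' has no attenuation coefficient; supply mu_per_m",
           m$name)
  }
  if (mu < 0) .stopf("mu must be >= 0 for material '%s'", m$name)
  list(delta = delta_free_electron(m, energy_kev, table),
       mu_per_m = mu, energy_kev = energy_kev)
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("Material table (%d materials): %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' @export
print.pcct_material <- function(x, ...) {
  cat(sprintf("Material '%s': rho=%.3f g/cm^3, Z=%g, A=%g g/mol, mu=%s /m\n",
              x$name, x$mass_density_g_cm3, x$electrons_per_unit,
              x$mass_per_unit_g_mol,
              ifelse(is.na(x$mu_per_m), "unset", format(x$mu_per_m))))
  invisible(x)
}
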