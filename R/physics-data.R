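#' Construct a material with energy-dependent photon interaction data
#'
#' A material bundles a linear attenuation table, Compton fractions,
#' geometric-progression (GP) buildup coefficients, a bulk density and an
#' effective atomic number. All tables share one strictly increasing energy
#' grid in MeV.
#'
#' @param name character identifier.
#' @param density bulk density in g/cm^3.
#' @param effective_Z effective atomic number, used to pick the branch of the
#'   Kalos two-region buildup rule.
#' @param E energy grid (MeV), strictly increasing.
#' @param mu linear attenuation coefficients (1/cm), positive, same length as `E`.
#' @param compton Compton fraction mu_C/mu in (0, 1], or `NULL` if unknown.
#' @param gp data.frame with columns `b`, `c`, `a`, `xK`, `d` (one row per
#'   energy node), or `NULL` if the material carries no buildup data.
#' @return an object of class `material`.
#' @export
material <- function(name, density, effective_Z, E, mu, compton = NULL, gp = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(density), density > 0,
            length(E) == length(mu))
  if (any(diff(E) <= 0)) stop("energy grid for material '", name, "' must be strictly increasing")
  if (any(mu <= 0)) stop("attenuation coefficients for material '", name, "' must be positive")
  if (!is.null(compton)) {
    stopifnot(length(compton) == length(E))
    if (any(compton <= 0 | compton > 1))
      stop("Compton fractions for material '", name, "' must lie in (0, 1]")
  }
  if (!is.null(gp)) {
    stopifnot(is.data.frame(gp), nrow(gp) == length(E),
              all(c("b", "c", "a", "xK", "d") %in% names(gp)))
    if (any(gp$b < 1)) stop("GP coefficient b must be >= 1 for material '", name, "'")
  }
  structure(list(name = name, density = density, effective_Z = effective_Z,
                 E = as.numeric(E), mu = as.numeric(mu),
                 compton = if (is.null(compton)) NULL else as.numeric(compton),
                 gp = gp),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  (rho = %g g/cm3, Zeff = %g, %d energy nodes %g-%g MeV%s)\n",
              x$name, x$density, x$effective_Z, length(x$E), min(x$E), max(x$E),
              if (is.null(x$gp)) ", no GP data" else ""))
  invisible(x)
}

.range_check <- function(E, grid, what, name) {
  bad <- E < grid[1] | E > grid[length(grid)]
  if (any(bad))
    stop(sprintf("energy %g MeV outside tabulated range [%g, %g] for %s '%s'",
                 E[which(bad)[1]], grid[1], grid[length(grid)], what, name))
}

# log-log table interpolation, exact at nodes
.loglog_interp <- function(E, grid, values) {
  exp(stats::approx(log(grid), log(values), xout = log(E), ties = "ordered")$y)
}

#' Interpolate the linear attenuation coefficient of a material
#'
#' Log-log interpolation between bracketing grid nodes; exact at nodes.
#'
#' @param material a [material()].
#' @param E photon energy in MeV (vectorized); must lie within the table range.
#' @return linear attenuation coefficient(s) in 1/cm.
#' @export
lookup_mu <- function(material, E) {
  .range_check(E, material$E, "material", material$name)
  .loglog_interp(E, material$E, material$mu)
}

#' Interpolate the Compton fraction mu_C/mu of a material
#'
#' Linear in log(energy); exact at nodes.
#'
#' @inheritParams lookup_mu
#' @return dimensionless Compton fraction(s) in (0, 1].
#' @export
lookup_compton_fraction <- function(material, E) {
  if (is.null(material$compton))
    stop("material '", material$name, "' has no Compton-fraction data")
  .range_check(E, material$E, "material", material$name)
  stats::approx(log(material$E), material$compton, xout = log(E), ties = "ordered")$y
}

#' Interpolate GP buildup coefficients of a material
#'
#' Each of the five coefficients is interpolated linearly in log(energy);
#' exact at grid nodes.
#'
#' @inheritParams lookup_mu
#' @param E a single photon energy in MeV.
#' @return a list with components `b`, `c`, `a`, `xK`, `d`.
#' @export
lookup_gp <- function(material, E) {
  if (is.null(material$gp))
    stop("material '", material$name, "' carries no GP buildup data")
  stopifnot(length(E) == 1L)
  .range_check(E, material$E, "material", material$name)
  lE <- log(material$E)
  out <- lapply(material$gp[c("b", "c", "a", "xK", "d")], function(v)
    stats::approx(lE, v, xout = log(E), ties = "ordered")$y)
  out
}

#' Interpolate a mass energy-absorption coefficient
#'
#' @param absorber an absorber table from [standard_library()] (`water` or `air`).
#' @param E photon energy in MeV (vectorized).
#' @return mass energy-absorption coefficient(s) in cm^2/g.
#' @export
lookup_mu_en <- function(absorber, E) {
  .range_check(E, absorber$E, "absorber", absorber$medium)
  .loglog_interp(E, absorber$E, absorber$mu_en_over_rho)
}

.read_header_value <- function(lines, key) {
  pat <- paste0("^#\\s*", key, ":\\s*")
  hit <- grep(pat, lines, value = TRUE)
  if (!length(hit)) stop("missing header field '", key, "'")
  sub(pat, "", hit[1])
}

.read_physics_table <- function(path) {
  if (!file.exists(path)) stop("packaged physics data file not found: ", path)
  lines <- readLines(path)
  dat <- tryCatch(utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#"),
                  error = function(e) stop("corrupt physics data file ", path, ": ", conditionMessage(e)))
  list(header = lines[startsWith(lines, "#")], data = dat)
}

.load_material_file <- function(path, name) {
  tb <- .read_physics_table(path)
  density <- as.numeric(.read_header_value(tb$header, "density_g_cm3"))
  Z <- as.numeric(.read_header_value(tb$header, "effective_Z"))
  d <- tb$data
  material(name, density, Z, d$E_MeV, d$mu_per_cm,
           compton = d$muC_over_mu,
           gp = d[, c("b", "c", "a", "xK", "d")])
}

.load_absorber_file <- function(path, medium) {
  tb <- .read_physics_table(path)
  d <- tb$data
  if (any(diff(d$E_MeV) <= 0) || any(d$mu_en_over_rho <= 0))
    stop("corrupt absorber table ", path)
  structure(list(medium = medium, E = d$E_MeV, mu_en_over_rho = d$mu_en_over_rho),
            class = "absorber_table")
}

.load_spectrum_file <- function(path, nuclide) {
  tb <- .read_physics_table(path)
  total <- as.numeric(.read_header_value(tb$header, "total_yield_per_decay"))
  d <- tb$data
  if (any(d$E_MeV <= 0) || any(d$yield <= 0)) stop("corrupt spectrum table ", path)
  # rescale so the yields sum exactly to the stated total
  yields <- d$yield * (total / sum(d$yield))
  structure(list(nuclide = nuclide,
                 lines = data.frame(E_MeV = d$E_MeV, yield = yields),
                 total_yield = total),
            class = "nuclide_spectrum")
}

.library_cache <- new.env(parent = emptyenv())

#' Load the packaged physics library
#'
#' Returns the materials (water, air, stainless steel, tungsten, 80%Pt/20%Fe
#' alloy, plastic), the water and air mass energy-absorption tables, and the
#' Cs-137 and Ir-192 line spectra shipped with the package. The Cs-137
#' spectrum is the single 0.662 MeV line with yield 0.851 photons per decay;
#' the Ir-192 spectrum is rescaled at load so its total yield is exactly
#' 2.364 photons per decay. Results are cached for the session.
#'
#' @return a list with components `materials` (named list of [material()]),
#'   `absorbers` (named list: `water`, `air`) and `spectra` (named list:
#'   `Cs-137`, `Ir-192`).
#' @export
standard_library <- function() {
  if (!is.null(.library_cache$lib)) return(.library_cache$lib)
  dir <- system.file("extdata", "physics", package = "brachydose")
  if (dir == "") stop("packaged physics data directory not found")
  mats <- list(
    water      = .load_material_file(file.path(dir, "material_water_synthetic.tsv"), "water"),
    air        = .load_material_file(file.path(dir, "material_air_synthetic.tsv"), "air"),
    steel      = .load_material_file(file.path(dir, "material_steel_synthetic.tsv"), "steel"),
    tungsten   = .load_material_file(file.path(dir, "material_tungsten_synthetic.tsv"), "tungsten"),
    ptfe_alloy = .load_material_file(file.path(dir, "material_ptfe_alloy_synthetic.tsv"), "ptfe_alloy"),
    plastic    = .load_material_file(file.path(dir, "material_plastic_synthetic.tsv"), "plastic")
  )
  lib <- list(
    materials = mats,
    absorbers = list(
      water = .load_absorber_file(file.path(dir, "absorber_water.tsv"), "water"),
      air   = .load_absorber_file(file.path(dir, "absorber_air.tsv"), "air")),
    spectra = list(
      "Cs-137" = .load_spectrum_file(file.path(dir, "spectrum_cs137.tsv"), "Cs-137"),
      "Ir-192" = .load_spectrum_file(file.path(dir, "spectrum_ir192_synthetic.tsv"), "Ir-192"))
  )
  .library_cache$lib <- lib
  lib
}
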