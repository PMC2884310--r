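#' Define an encapsulated (line or point) radioactive source
#'
#' Models a sealed source: a cylindrical active core of `active_length` x
#' `active_diameter` centred on `axis`, inside a capsule of
#' `capsule_outer_diameter` and `capsule_length`. `active_offset` shifts the
#' active core centre along the axis relative to the capsule centre
#' (positive toward +axis), e.g. for tube sources with a thick closed end.
#' A zero `active_length` denotes a point source.
#'
#' @param nuclide `"Cs-137"` or `"Ir-192"` (must exist in the library's spectra).
#' @param active_length,active_diameter active core dimensions, cm.
#' @param capsule_outer_diameter,capsule_length capsule dimensions, cm.
#' @param capsule_material a [material()] (e.g. steel).
#' @param center capsule centre, 3-vector cm.
#' @param axis source axis (normalized internally).
#' @param strength list with `value` and `unit`, one of
#'   `"uGy_h_m2"` (air-kerma strength S_k), `"uGy_h_m2_per_cm"` (linear
#'   reference air-kerma rate, converted over the source's nominal capsule
#'   length), or `"Bq"` (activity).
#' @param active_offset axial offset of the active core centre from the
#'   capsule centre, cm.
#' @param label optional name used in plan tables.
#' @return an object of class `encapsulated_source`.
#' @export
encapsulated_source <- function(nuclide, active_length, active_diameter,
                                capsule_outer_diameter, capsule_length,
                                capsule_material, center, axis,
                                strength, active_offset = 0, label = nuclide) {
  stopifnot(active_length >= 0, active_diameter > 0,
            active_diameter < capsule_outer_diameter,
            capsule_length >= active_length,
            inherits(capsule_material, "material"))
  if (!is.list(strength) || is.null(strength$value) || is.null(strength$unit))
    stop("strength must be list(value =, unit =)")
  structure(list(nuclide = nuclide, active_length = active_length,
                 active_diameter = active_diameter,
                 capsule_outer_diameter = capsule_outer_diameter,
                 capsule_length = capsule_length,
                 capsule_material = capsule_material,
                 center = as.numeric(center), axis = .unit(axis),
                 strength = strength, active_offset = active_offset,
                 label = label),
            class = "encapsulated_source")
}

# J/MeV, g/kg, s/h and cGy/Gy folded into one fluence-to-dose constant:
# cGy/h per (photons/s * MeV * cm^2/g / cm^2)
.DOSE_CONST <- 1.602e-13 * 1e3 * 3600 * 100

#' Air-kerma rate constant of a nuclide
#'
#' Unfiltered point-source air-kerma rate at 1 m per unit activity, computed
#' from the line spectrum and the air mass energy-absorption coefficients:
#' \eqn{\Gamma = \sum_i p_i E_i (\mu_{en}/\rho)_{air}(E_i) \cdot
#'   1.602\times10^{-13} \cdot 10^3 \cdot 3600 / (4\pi \cdot 100^2)}
#' in Gy/h per Bq, returned in uGy h^-1 m^2 / Bq.
#'
#' @param nuclide nuclide identifier present in `library$spectra`.
#' @param library a physics library from [standard_library()].
#' @return kerma-rate constant in uGy h^-1 m^2 per Bq.
#' @export
kerma_rate_constant <- function(nuclide, library = standard_library()) {
  sp <- library$spectra[[nuclide]]
  if (is.null(sp)) stop("unknown nuclide '", nuclide, "'")
  muen <- lookup_mu_en(library$absorbers$air, sp$lines$E_MeV)
  k_gy_h <- sum(sp$lines$yield * sp$lines$E_MeV * muen) *
    1.602e-13 * 1e3 * 3600 / (4 * pi * 100^2)
  k_gy_h * 1e6
}

#' Capsule-filtered kerma-rate constant of an encapsulated source
#'
#' Air-kerma strength is an output-referenced quantity: it is stated for the
#' assembled, encapsulated source. Because the dose engine traces every ray
#' explicitly through the capsule wall, converting a stated strength with the
#' bare-nuclide [kerma_rate_constant()] would count the encapsulation twice.
#' This variant attenuates each spectrum line through the radial capsule wall
#' thickness (with its GP buildup factor) before summing, giving the constant
#' that maps *contained* activity to the stated transverse-plane strength.
#'
#' @param source an [encapsulated_source()].
#' @param library a physics library.
#' @return filtered kerma-rate constant in uGy h^-1 m^2 per Bq.
#' @export
source_kerma_constant <- function(source, library = standard_library()) {
  sp <- library$spectra[[source$nuclide]]
  if (is.null(sp)) stop("unknown nuclide '", source$nuclide, "'")
  t_wall <- (source$capsule_outer_diameter - source$active_diameter) / 2
  E <- sp$lines$E_MeV
  muen <- lookup_mu_en(library$absorbers$air, E)
  filt <- vapply(seq_along(E), function(i) {
    l <- lookup_mu(source$capsule_material, E[i]) * t_wall
    exp(-l) * gp_buildup(lookup_gp(source$capsule_material, E[i]), l)
  }, 0)
  k_gy_h <- sum(sp$lines$yield * E * muen * filt) *
    1.602e-13 * 1e3 * 3600 / (4 * pi * 100^2)
  k_gy_h * 1e6
}

#' Convert a stated source strength to contained activity
#'
#' Air-kerma strengths are divided by the source's capsule-filtered
#' [source_kerma_constant()]; linear reference air-kerma rates are first
#' multiplied by the source's nominal (capsule) length. If an activity is
#' supplied directly it is used as is. If a strength additionally carries a
#' vendor `activity_Bq` cross-check that disagrees with the kerma-derived
#' activity by more than 5%, a warning is raised and the air-kerma value wins
#' (the clinical standard quantity).
#'
#' @param source an [encapsulated_source()].
#' @param library a physics library.
#' @return activity in Bq.
#' @export
strength_to_activity <- function(source, library = standard_library()) {
  s <- source$strength
  sk <- switch(s$unit,
    Bq = return(s$value),
    uGy_h_m2 = s$value,
    uGy_h_m2_per_cm = s$value * source$capsule_length,
    stop("unknown strength unit '", s$unit, "'"))
  if (sk == 0) return(0)
  A <- sk / source_kerma_constant(source, library)
  if (!is.null(s$activity_Bq) && abs(s$activity_Bq / A - 1) > 0.05)
    warning(sprintf("source '%s': stated activity %.3g Bq disagrees with air-kerma-derived %.3g Bq by >5%%; using the air-kerma value",
                    source$label, s$activity_Bq, A))
  A
}

#' Discretize a source into point emitters
#'
#' The active core is split into `n = ceiling(active_length / delta_l)` equal
#' segments; one emitter sits at each segment centre on the source axis and
#' carries `activity / n`. A zero-length source yields a single emitter at
#' the active centre. Total emission is conserved exactly.
#'
#' @param source an [encapsulated_source()].
#' @param delta_l segment length in cm, `> 0`.
#' @param library a physics library (for the strength conversion).
#' @return data.frame with columns `x`, `y`, `z` (cm) and `activity` (Bq).
#' @export
discretize <- function(source, delta_l = 0.005, library = standard_library()) {
  stopifnot(delta_l > 0)
  A <- strength_to_activity(source, library)
  c0 <- source$center + source$active_offset * source$axis
  if (source$active_length == 0) {
    pos <- matrix(c0, ncol = 3)
  } else {
    n <- ceiling(source$active_length / delta_l)
    s <- (seq_len(n) - 0.5) / n * source$active_length - source$active_length / 2
    pos <- matrix(rep(c0, each = n), ncol = 3) + outer(s, source$axis)
  }
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             activity = A / nrow(pos))
}

# capsule + active-core geometry regions for a source (priority base prio)
.source_regions <- function(source, library, prio) {
  half <- source$capsule_length / 2
  base <- source$center - half * source$axis
  caps <- region(source$capsule_material,
                 prim_cylinder(base, source$axis, source$capsule_outer_diameter / 2,
                               source$capsule_length),
                 priority = prio)
  c0 <- source$center + source$active_offset * source$axis
  al <- max(source$active_length, 1e-3)   # point sources get a token core
  core_base <- c0 - al / 2 * source$axis
  core <- region(library$materials$water,
                 prim_cylinder(core_base, source$axis, source$active_diameter / 2, al),
                 priority = prio + 1L, is_source_core = TRUE)
  list(caps, core)
}
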