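#' @name applicators
#' @title Intracavitary applicator builders
#'
#' @description Builders return a list with `geometry`, `sources` and some
#'   descriptive metadata, ready for [dose_model()]. The coordinate frame has
#'   its origin at the external os on the tandem axis, +y superior along the
#'   straight tandem, +x patient-left and +z anterior; tandem angulation
#'   rotates the tandem assembly anteriorly (toward +z) about the os.
#'   Manchester point A is (±2, 2, 0) cm and point B (±5, 2, 0) cm in this
#'   frame.
NULL

.rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

# tube sources stacked end to end from the inner (fundus) tip downward;
# returns capsule centres (distance below the tip along the tube axis)
.stack_centers <- function(tip, capsule_lengths) {
  tops <- tip - c(0, cumsum(capsule_lengths))[seq_along(capsule_lengths)]
  tops - capsule_lengths / 2
}

#' @rdname applicators
#'
#' @details `build_brit_ldr()` models the tandem-and-ovoid LDR assembly with
#'   CSA-1/CSA-2 Cs-137 tube sources (active 1.5/1.0 cm x 0.18 cm, capsule OD
#'   0.3 cm steel, nominal capsule length 2.0 cm, 1 mm closed end facing the
#'   fundus). The long tandem carries 350/230/230 uGy h^-1 m^2 from the
#'   fundus, the medium tandem 350/230; each ovoid holds one 230 uGy h^-1 m^2
#'   CSA-2. Applicator walls are steel tubes of 0.5 cm ID / 0.6 cm OD.
#'
#' @param tandem `"long"` (3 sources) or `"medium"` (2 sources).
#' @param angulation_deg anterior tandem angulation about the os; the studied
#'   range is 0-40 degrees (values outside give a warning, not an error).
#' @param ovoid_separation_cm separation between ovoid source centres (studied
#'   range 2.5-4.0 cm).
#' @param ovoid_depth_cm depth of the ovoid centres below the os (studied
#'   range 1.25-2.0 cm).
#' @param walls if `FALSE`, a sources-only model: identical source positions,
#'   no applicator tubes.
#' @param ovoid_tilt_deg ovoid source axis tilt in the sagittal plane.
#' @param library physics library.
#' @export
build_brit_ldr <- function(tandem = c("long", "medium"), angulation_deg = 0,
                           ovoid_separation_cm = 3.0, ovoid_depth_cm = 1.5,
                           walls = TRUE, ovoid_tilt_deg = -40,
                           library = standard_library()) {
  tandem <- match.arg(tandem)
  if (angulation_deg < 0 || angulation_deg > 45)
    warning("tandem angulation ", angulation_deg, " deg outside the studied 0-45 range")
  if (ovoid_separation_cm < 2.5 || ovoid_separation_cm > 4.0)
    warning("ovoid separation ", ovoid_separation_cm, " cm outside the studied 2.5-4.0 range")
  if (ovoid_depth_cm < 1.25 || ovoid_depth_cm > 2.0)
    warning("ovoid depth ", ovoid_depth_cm, " cm outside the studied 1.25-2.0 range")
  steel <- library$materials$steel
  R <- .rot_x(angulation_deg)
  tand_axis <- as.numeric(R %*% c(0, 1, 0))

  cs_tube <- function(center, axis, label, sk, active_len) {
    # 1 mm closed end at the fundus side: active core sits 1 mm below the
    # capsule's +axis end
    offset <- 1.0 - 0.1 - active_len / 2
    encapsulated_source("Cs-137", active_len, 0.18, 0.3, 2.0, steel,
                        center, axis,
                        strength = list(value = sk, unit = "uGy_h_m2"),
                        active_offset = offset, label = label)
  }

  tip <- 6.0
  if (tandem == "long") {
    sk <- c(350, 230, 230); lens <- c(1.5, 1.0, 1.0)
    labels <- c("S1_fundus", "S2_middle", "S3_lower")
  } else {
    sk <- c(350, 230); lens <- c(1.5, 1.0)
    labels <- c("S1_fundus", "S2_lower")
  }
  centers_1d <- .stack_centers(tip, rep(2.0, length(sk)))
  tandem_sources <- lapply(seq_along(sk), function(i)
    cs_tube(as.numeric(R %*% c(0, centers_1d[i], 0)), tand_axis,
            labels[i], sk[i], lens[i]))

  ov_axis <- as.numeric(.rot_x(ovoid_tilt_deg) %*% c(0, 1, 0))
  ov_centers <- list(c(+ovoid_separation_cm / 2, -ovoid_depth_cm, 0),
                     c(-ovoid_separation_cm / 2, -ovoid_depth_cm, 0))
  ovoid_sources <- lapply(1:2, function(i)
    cs_tube(ov_centers[[i]], ov_axis, c("S4_right", "S5_left")[i], 230, 1.0))

  sources <- c(tandem_sources, ovoid_sources)
  regions <- list()
  if (walls) {
    # steel annulus only: the lumen stays ambient, matching the homogenized
    # applicator convention of the reconstructed code (an explicit air gap
    # would partially offset the wall attenuation; see the methods vignette)
    tube <- function(base, axis, len, prio) list(
      region(steel, prim_cylinder(base, axis, 0.30, len),
             exclude = prim_cylinder(base, axis, 0.25, len - 0.1),
             priority = prio))
    # the intrauterine tube continues 4 cm below the os toward the handle;
    # rays from an ovoid source to the contralateral reference points cross it
    regions <- c(regions, tube(c(0, -4, 0), tand_axis, tip + 0.15 + 4, 10L))
    for (ctr in ov_centers)
      regions <- c(regions, tube(ctr - 1.2 * ov_axis, ov_axis, 2.4, 10L))
  }
  for (i in seq_along(sources))
    regions <- c(regions, .source_regions(sources[[i]], library, 20L + 2L * i))
  list(geometry = geometry(regions, ambient = library$materials$water),
       sources = sources, applicator = "brit_ldr",
       params = list(tandem = tandem, angulation_deg = angulation_deg,
                     ovoid_separation_cm = ovoid_separation_cm,
                     ovoid_depth_cm = ovoid_depth_cm, walls = walls,
                     ovoid_tilt_deg = ovoid_tilt_deg))
}

#' @rdname applicators
#'
#' @details `build_fletcher_green()` models the Fletcher Green type LDR
#'   loading with CDC-J Cs-137 tube sources (active 1.35 cm x 0.165 cm,
#'   capsule OD 0.265 cm of 80%Pt/20%Fe at 21.644 g/cm^3, nominal capsule
#'   length 2.0 cm). Tandem linear reference air-kerma rates are
#'   54.2/36.2/36.2 uGy h^-1 m^2 cm^-1 from the fundus; the colpostats carry
#'   a total of 72.3 uGy h^-1 m^2 cm^-1 split equally. Only the sources are
#'   modeled (sources-only), matching how this applicator is evaluated.
#'
#' @param tilt_deg anterior tandem tilt (15 degrees for the standard loading).
#' @export
build_fletcher_green <- function(tilt_deg = 15, ovoid_separation_cm = 3.0,
                                 ovoid_depth_cm = 1.5, ovoid_tilt_deg = 30,
                                 library = standard_library()) {
  alloy <- library$materials$ptfe_alloy
  R <- .rot_x(tilt_deg)
  tand_axis <- as.numeric(R %*% c(0, 1, 0))
  cdc <- function(center, axis, label, rakr) {
    encapsulated_source("Cs-137", 1.35, 0.165, 0.265, 2.0, alloy, center, axis,
                        strength = list(value = rakr, unit = "uGy_h_m2_per_cm"),
                        label = label)
  }
  centers_1d <- .stack_centers(6.0, rep(2.0, 3))
  rakr <- c(54.2, 36.2, 36.2)
  tandem_sources <- lapply(1:3, function(i)
    cdc(as.numeric(R %*% c(0, centers_1d[i], 0)), tand_axis,
        c("S1_fundus", "S2_middle", "S3_lower")[i], rakr[i]))
  ov_axis <- as.numeric(.rot_x(ovoid_tilt_deg) %*% c(0, 1, 0))
  ov_centers <- list(c(+ovoid_separation_cm / 2, -ovoid_depth_cm, 0),
                     c(-ovoid_separation_cm / 2, -ovoid_depth_cm, 0))
  ovoid_sources <- lapply(1:2, function(i)
    cdc(ov_centers[[i]], ov_axis, c("S4_right", "S5_left")[i], 72.3 / 2))
  sources <- c(tandem_sources, ovoid_sources)
  regions <- list()
  for (i in seq_along(sources))
    regions <- c(regions, .source_regions(sources[[i]], library, 20L + 2L * i))
  list(geometry = geometry(regions, ambient = library$materials$water),
       sources = sources, applicator = "fletcher_green",
       params = list(tilt_deg = tilt_deg, ovoid_separation_cm = ovoid_separation_cm,
                     ovoid_depth_cm = ovoid_depth_cm, ovoid_tilt_deg = ovoid_tilt_deg))
}

#' @rdname applicators
#'
#' @details `build_fletcher_williamson()` models the HDR plan: an mHDR Ir-192
#'   source (active 0.36 cm x 0.065 cm, steel capsule OD 0.09 cm) stepped
#'   through 20 dwell positions — 14 in the tandem at 5 mm steps from the
#'   fundus and 3 in each ovoid — each dwell represented as a source of the
#'   stated air-kerma strength weighted by its dwell time. Sources-only.
#'
#' @param sk_uGy_h_m2 source air-kerma strength (default 40700, a nominal
#'   10 Ci HDR source).
#' @param dwell_times_s dwell times, length 20 (tandem fundus-down, then
#'   right ovoid, then left ovoid); equal weights by default.
#' @export
build_fletcher_williamson <- function(tilt_deg = 15, ovoid_separation_cm = 3.0,
                                      ovoid_depth_cm = 1.5, ovoid_tilt_deg = 30,
                                      sk_uGy_h_m2 = 40700,
                                      dwell_times_s = rep(1, 20),
                                      library = standard_library()) {
  stopifnot(length(dwell_times_s) == 20, all(dwell_times_s >= 0))
  steel <- library$materials$steel
  w <- dwell_times_s / sum(dwell_times_s)
  R <- .rot_x(tilt_deg)
  tand_axis <- as.numeric(R %*% c(0, 1, 0))
  mhdr <- function(center, axis, label, wt) {
    encapsulated_source("Ir-192", 0.36, 0.065, 0.09, 0.45, steel, center, axis,
                        strength = list(value = sk_uGy_h_m2 * wt, unit = "uGy_h_m2"),
                        label = label)
  }
  tandem_y <- 6.0 - 0.5 * (0:13)
  sources <- lapply(1:14, function(i)
    mhdr(as.numeric(R %*% c(0, tandem_y[i], 0)), tand_axis,
         sprintf("T%02d", i), w[i]))
  ov_axis <- as.numeric(.rot_x(ovoid_tilt_deg) %*% c(0, 1, 0))
  k <- 15L
  for (side in c(+1, -1)) {
    ctr <- c(side * ovoid_separation_cm / 2, -ovoid_depth_cm, 0)
    for (s in c(-0.5, 0, 0.5)) {
      sources[[k]] <- mhdr(ctr + s * ov_axis, ov_axis,
                           sprintf("%s%d", if (side > 0) "OR" else "OL",
                                   (k - 15L) %% 3L + 1L), w[k])
      k <- k + 1L
    }
  }
  regions <- list()
  for (i in seq_along(sources))
    regions <- c(regions, .source_regions(sources[[i]], library, 20L + 2L * i))
  list(geometry = geometry(regions, ambient = library$materials$water),
       sources = sources, applicator = "fletcher_williamson",
       params = list(tilt_deg = tilt_deg, ovoid_separation_cm = ovoid_separation_cm,
                     ovoid_depth_cm = ovoid_depth_cm, sk_uGy_h_m2 = sk_uGy_h_m2))
}

#' @rdname applicators
#'
#' @details `build_vaginal_cylinder()` models the shielded vaginal cylinder
#'   set: a 15 cm long plastic shell (OD 3.0 cm, 0.5 cm wall) on a central
#'   steel tube (OD 0.4 cm), an air gap, and an optional 0.8 cm thick
#'   tungsten sector shield of 90, 180 or 270 degrees centred on the
#'   posterior (azimuth 180) direction. Azimuth 0 is the unshielded +z
#'   reference, increasing toward +x. A single mHDR Ir-192 source of 1 Ci
#'   (3.7e10 Bq) sits on the axis 4.5 cm from the applicator tip.
#'
#' @param shield_angle_deg 0 (unshielded control), 90, 180 or 270.
#' @param activity_Bq source activity (default 1 Ci).
#' @export
build_vaginal_cylinder <- function(shield_angle_deg = 180, activity_Bq = 3.7e10,
                                   library = standard_library()) {
  if (!shield_angle_deg %in% c(0, 90, 180, 270))
    stop("shield_angle_deg must be one of 0, 90, 180, 270")
  steel <- library$materials$steel
  axis <- c(0, 1, 0)
  tip <- 15
  src_y <- tip - 4.5
  source <- encapsulated_source("Ir-192", 0.36, 0.065, 0.09, 0.45, steel,
                                c(0, src_y, 0), axis,
                                strength = list(value = activity_Bq, unit = "Bq"),
                                label = "mHDR")
  regions <- list(
    region(library$materials$plastic, prim_cylinder(c(0, 0, 0), axis, 1.5, tip),
           priority = 5L),
    region(library$materials$air, prim_cylinder(c(0, 0, 0), axis, 1.0, tip - 0.5),
           priority = 6L),
    region(steel, prim_cylinder(c(0, 0, 0), axis, 0.2, tip - 0.2), priority = 8L),
    region(library$materials$air, prim_cylinder(c(0, 0, 0), axis, 0.15, tip - 0.3),
           priority = 9L)
  )
  if (shield_angle_deg > 0) {
    half <- shield_angle_deg / 2
    regions <- c(regions, list(
      region(library$materials$tungsten,
             prim_sector_shell(c(0, 4, 0), axis, r_inner = 0.2, r_outer = 1.0,
                               length = 10.8,
                               angle_start = 180 - half, angle_stop = 180 + half,
                               ref = c(0, 0, 1)),
             priority = 7L)))
  }
  regions <- c(regions, .source_regions(source, library, 20L))
  list(geometry = geometry(regions, ambient = library$materials$water),
       sources = list(source), applicator = "vaginal_cylinder",
       params = list(shield_angle_deg = shield_angle_deg, activity_Bq = activity_Bq,
                     source_center = c(0, src_y, 0), outer_radius = 1.5))
}
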