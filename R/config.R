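#' @name plan_config
#' @title Plan configuration files
#'
#' @description Plans are described by plain-text YAML files with an
#'   `applicator` block (builder name plus its parameters, or `custom` with an
#'   explicit `sources` list), an optional `computation` block (`delta_l_cm`,
#'   `unit`), an optional `points` block (named 3-vectors; the Manchester
#'   defaults are used when absent), and optional `grid` / `isodose` /
#'   `profile` blocks consumed by the corresponding commands. Units are
#'   explicit in key names; the engine is deterministic, so configs carry no
#'   seeds. [read_plan_config()] parses and validates; [build_plan()] turns a
#'   config into a [dose_model()].
NULL

.cfg_need <- function(block, field, where) {
  if (is.null(block[[field]]))
    stop("plan config: missing field '", field, "' in ", where)
  block[[field]]
}

.cfg_num3 <- function(v, what) {
  v <- as.numeric(unlist(v))
  if (length(v) != 3 || anyNA(v)) stop("plan config: '", what, "' must be a numeric 3-vector")
  v
}

#' @rdname plan_config
#' @param path path to a YAML plan configuration.
#' @return `read_plan_config()`: the validated config list (class `plan_config`).
#' @export
read_plan_config <- function(path) {
  if (!file.exists(path)) stop("plan config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  app <- .cfg_need(cfg, "applicator", "top level")
  type <- .cfg_need(app, "type", "'applicator'")
  known <- c("brit_ldr", "fletcher_green", "fletcher_williamson",
             "vaginal_cylinder", "custom")
  if (!type %in% known)
    stop("plan config: unknown applicator type '", type, "' (field 'applicator.type'); ",
         "expected one of: ", paste(known, collapse = ", "))
  if (type == "custom") {
    srcs <- .cfg_need(app, "sources", "'applicator' (custom)")
    for (i in seq_along(srcs)) {
      s <- srcs[[i]]
      for (f in c("nuclide", "center_cm", "axis", "strength"))
        .cfg_need(s, f, sprintf("'applicator.sources[%d]'", i))
      st <- s$strength
      .cfg_need(st, "value", sprintf("'applicator.sources[%d].strength'", i))
      .cfg_need(st, "unit", sprintf("'applicator.sources[%d].strength'", i))
    }
  }
  comp <- cfg$computation
  if (!is.null(comp$unit) && !comp$unit %in% c("cGy/h", "Gy/h"))
    stop("plan config: 'computation.unit' must be cGy/h or Gy/h")
  if (!is.null(comp$delta_l_cm) && comp$delta_l_cm <= 0)
    stop("plan config: 'computation.delta_l_cm' must be positive")
  structure(cfg, class = c("plan_config", "list"))
}

#' @rdname plan_config
#' @param config a `plan_config` (or path to one).
#' @param library physics library.
#' @return `build_plan()`: a [dose_model()].
#' @export
build_plan <- function(config, library = standard_library()) {
  if (is.character(config)) config <- read_plan_config(config)
  app <- config$applicator
  comp <- config$computation
  delta_l <- if (is.null(comp$delta_l_cm)) 0.005 else comp$delta_l_cm
  unit <- if (is.null(comp$unit)) "cGy/h" else comp$unit
  pick <- function(args, defaults) {
    keep <- intersect(names(args), names(defaults))
    utils::modifyList(defaults, args[keep])
  }
  built <- switch(app$type,
    brit_ldr = do.call(build_brit_ldr, c(pick(app, list(
      tandem = "long", angulation_deg = 0, ovoid_separation_cm = 3.0,
      ovoid_depth_cm = 1.5, walls = TRUE, ovoid_tilt_deg = -40)),
      list(library = library))),
    fletcher_green = do.call(build_fletcher_green, c(pick(app, list(
      tilt_deg = 15, ovoid_separation_cm = 3.0, ovoid_depth_cm = 1.5,
      ovoid_tilt_deg = 30)), list(library = library))),
    fletcher_williamson = do.call(build_fletcher_williamson, c(pick(app, list(
      tilt_deg = 15, ovoid_separation_cm = 3.0, ovoid_depth_cm = 1.5,
      ovoid_tilt_deg = 30, sk_uGy_h_m2 = 40700,
      dwell_times_s = rep(1, 20))), list(library = library))),
    vaginal_cylinder = do.call(build_vaginal_cylinder, c(pick(app, list(
      shield_angle_deg = 180, activity_Bq = 3.7e10)), list(library = library))),
    custom = {
      srcs <- lapply(app$sources, function(s) {
        mat <- library$materials[[if (is.null(s$capsule_material)) "steel" else s$capsule_material]]
        if (is.null(mat)) stop("plan config: unknown capsule material '", s$capsule_material, "'")
        encapsulated_source(
          nuclide = s$nuclide,
          active_length = if (is.null(s$active_length_cm)) 0 else s$active_length_cm,
          active_diameter = if (is.null(s$active_diameter_cm)) 0.05 else s$active_diameter_cm,
          capsule_outer_diameter = if (is.null(s$capsule_outer_diameter_cm)) 0.1 else s$capsule_outer_diameter_cm,
          capsule_length = if (is.null(s$capsule_length_cm)) max(0.5, if (is.null(s$active_length_cm)) 0 else s$active_length_cm) else s$capsule_length_cm,
          capsule_material = mat,
          center = .cfg_num3(s$center_cm, "center_cm"),
          axis = .cfg_num3(s$axis, "axis"),
          strength = list(value = s$strength$value, unit = s$strength$unit),
          label = if (is.null(s$label)) s$nuclide else s$label)
      })
      regions <- list()
      bare <- isTRUE(app$bare_emitters)
      if (!bare)
        for (i in seq_along(srcs))
          regions <- c(regions, .source_regions(srcs[[i]], library, 20L + 2L * i))
      list(geometry = geometry(regions, ambient = library$materials$water),
           sources = srcs, applicator = "custom", params = app)
    })
  dose_model(built, delta_l = delta_l, library = library, unit = unit)
}

.config_points <- function(config) {
  if (is.null(config$points)) return(reference_points())
  pts <- config$points
  if (is.null(names(pts)) || anyDuplicated(names(pts)))
    stop("plan config: 'points' must be a uniquely named map of 3-vectors")
  do.call(rbind, lapply(names(pts), function(nm) {
    v <- .cfg_num3(pts[[nm]], paste0("points.", nm))
    data.frame(point = nm, x = v[1], y = v[2], z = v[3])
  }))
}

#' Write a plan dose table as delimited text
#'
#' @param table a data.frame from [evaluate_plan()] or [angular_profile()].
#' @param path output file.
#' @param meta optional named character vector written as `# key: value` headers.
#' @export
write_dose_table <- function(table, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), unname(meta)), con)
  utils::write.table(table, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @name cli_commands
#' @title Command-level operations behind the CLI
#'
#' @description These functions implement the `compute-points`,
#'   `compute-grid`, `isodose` and `fixtures` commands of the shipped
#'   `inst/cli/brachydose` script; they are exported so plans can be driven
#'   from R directly. All outputs are delimited text with self-describing
#'   `#` headers; identical configs give byte-identical tables.
NULL

#' @rdname cli_commands
#' @param config_path path to a YAML plan config.
#' @param output output file path.
#' @param library physics library.
#' @return the output path, invisibly.
#' @export
cmd_compute_points <- function(config_path, output, library = standard_library()) {
  cfg <- read_plan_config(config_path)
  model <- build_plan(cfg, library)
  message(sprintf("geometry: %d regions; %d emitters (delta_l = %g cm)",
                  length(model$geometry$regions), nrow(model$emitters), model$delta_l))
  if (!is.null(cfg$profile)) {
    pr <- cfg$profile
    tab <- angular_profile(model,
                           radii = if (is.null(pr$radii_cm)) seq(1.5, 11, 0.5) else as.numeric(unlist(pr$radii_cm)),
                           angles = if (is.null(pr$angles_deg)) seq(0, 180, 5) else as.numeric(unlist(pr$angles_deg)),
                           mirror = isTRUE(pr$mirror))
  } else {
    tab <- evaluate_plan(model, .config_points(cfg),
                         per_source = isTRUE(cfg$computation$per_source))
    tab$dose_rate <- signif(tab$dose_rate, 9)
  }
  write_dose_table(tab, output,
                   meta = c(applicator = model$applicator,
                            delta_l_cm = format(model$delta_l), unit = model$unit))
  invisible(output)
}

#' @rdname cli_commands
#' @export
cmd_compute_grid <- function(config_path, output, library = standard_library()) {
  cfg <- read_plan_config(config_path)
  g <- .cfg_need(cfg, "grid", "top level")
  model <- build_plan(cfg, library)
  grid <- dose_rate_grid(model,
                         origin = .cfg_num3(.cfg_need(g, "origin_cm", "'grid'"), "grid.origin_cm"),
                         spacing = as.numeric(unlist(.cfg_need(g, "spacing_cm", "'grid'"))),
                         dims = as.integer(unlist(.cfg_need(g, "dims", "'grid'"))),
                         delta_l = if (is.null(g$delta_l_cm)) 0.05 else g$delta_l_cm)
  pts <- expand.grid(x = grid$x, y = grid$y, z = grid$z)
  pts$value <- as.numeric(grid$values)
  write_dose_table(pts, output,
                   meta = c(origin_cm = paste(grid$origin, collapse = " "),
                            spacing_cm = paste(grid$spacing, collapse = " "),
                            shape = paste(grid$dims, collapse = " "),
                            unit = grid$unit))
  invisible(output)
}

#' @rdname cli_commands
#' @param plane_axis,offset contour plane (override the config's `isodose` block).
#' @param levels contour levels (percent if a normalization point is given).
#' @export
cmd_isodose <- function(config_path, output, plane_axis = NULL, offset = NULL,
                        levels = NULL, library = standard_library()) {
  cfg <- read_plan_config(config_path)
  g <- .cfg_need(cfg, "grid", "top level")
  iso <- if (is.null(cfg$isodose)) list() else cfg$isodose
  if (!is.null(plane_axis)) iso$plane_axis <- plane_axis
  if (!is.null(offset)) iso$offset <- offset
  if (!is.null(levels)) iso$levels <- levels
  if (is.null(iso$levels)) stop("plan config: no isodose levels given ('isodose.levels')")
  model <- build_plan(cfg, library)
  grid <- dose_rate_grid(model,
                         origin = .cfg_num3(.cfg_need(g, "origin_cm", "'grid'"), "grid.origin_cm"),
                         spacing = as.numeric(unlist(.cfg_need(g, "spacing_cm", "'grid'"))),
                         dims = as.integer(unlist(.cfg_need(g, "dims", "'grid'"))),
                         delta_l = if (is.null(g$delta_l_cm)) 0.05 else g$delta_l_cm)
  normalize <- NULL
  if (!is.null(iso$normalize_at_cm)) {
    np <- .cfg_num3(iso$normalize_at_cm, "isodose.normalize_at_cm")
    normalize <- dose_rate(model, np)
  }
  ct <- extract_contours(grid,
                         plane_axis = if (is.null(iso$plane_axis)) "z" else iso$plane_axis,
                         offset = if (is.null(iso$offset)) 0 else iso$offset,
                         levels = as.numeric(unlist(iso$levels)),
                         normalize = normalize)
  write_contours(ct, output)
  invisible(output)
}

#' @rdname cli_commands
#' @param dir output directory for the example configs.
#' @return `cmd_fixtures()`: character vector of written file paths, invisibly.
#' @export
cmd_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fixtures <- list(
    brit_standard = list(
      applicator = list(type = "brit_ldr", tandem = "long", angulation_deg = 0,
                        ovoid_separation_cm = 3.0, ovoid_depth_cm = 1.5, walls = TRUE),
      computation = list(delta_l_cm = 0.005, unit = "cGy/h", per_source = TRUE)),
    brit_sources_only = list(
      applicator = list(type = "brit_ldr", tandem = "long", angulation_deg = 0,
                        ovoid_separation_cm = 3.0, ovoid_depth_cm = 1.5, walls = FALSE),
      computation = list(delta_l_cm = 0.005, unit = "cGy/h", per_source = TRUE)),
    fletcher_green = list(
      applicator = list(type = "fletcher_green", tilt_deg = 15,
                        ovoid_separation_cm = 3.0, ovoid_depth_cm = 1.5,
                        ovoid_tilt_deg = 30),
      computation = list(delta_l_cm = 0.005, unit = "cGy/h")),
    fletcher_williamson = list(
      applicator = list(type = "fletcher_williamson", tilt_deg = 15,
                        ovoid_separation_cm = 3.0, sk_uGy_h_m2 = 40700),
      computation = list(delta_l_cm = 0.005, unit = "Gy/h")),
    toy_point_source = list(
      applicator = list(type = "custom", bare_emitters = TRUE, sources = list(list(
        nuclide = "Cs-137", center_cm = c(0, 0, 0), axis = c(0, 1, 0),
        strength = list(value = 1e9, unit = "Bq"), label = "bare_point"))),
      computation = list(delta_l_cm = 0.005, unit = "cGy/h"),
      points = list(p1cm = c(1, 0, 0), p2cm = c(2, 0, 0)),
      grid = list(origin_cm = c(-3, -3, 0), spacing_cm = 0.25, dims = c(25, 25, 1)),
      isodose = list(plane_axis = "z", offset = 0, levels = c(100, 50),
                     normalize_at_cm = c(1, 0, 0)))
  )
  for (ang in c(90, 180, 270)) {
    fixtures[[sprintf("vaginal_cylinder_%d", ang)]] <- list(
      applicator = list(type = "vaginal_cylinder", shield_angle_deg = ang,
                        activity_Bq = 3.7e10),
      computation = list(delta_l_cm = 0.05, unit = "cGy/h"),
      profile = list(radii_cm = seq(1.5, 11, 0.5), angles_deg = seq(0, 180, 5),
                     mirror = TRUE))
  }
  paths <- character(0)
  for (nm in names(fixtures)) {
    p <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(fixtures[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
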