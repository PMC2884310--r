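#' Assemble a dose model
#'
#' The central object of the package: a geometry, a set of encapsulated
#' sources discretized into point emitters, their line spectra, and the
#' ambient absorber used for the fluence-to-dose conversion. All dose queries
#' ([dose_rate()], [evaluate_plan()], [dose_rate_grid()], [angular_profile()],
#' [predict.dose_model()]) run against it.
#'
#' For every emitter/line the engine evaluates the point kernel
#' \deqn{\dot D = \sum_e \sum_i \frac{A_e\,p_i\,E_i}{4\pi d_e^2}
#'   e^{-\sum_j \mu_j(E_i)\,t_j}\; B_{\mathrm{eff}}(E_i)\;
#'   (\mu_{en}/\rho)_w(E_i)\; \kappa}
#' with the per-material path lengths \eqn{t_j} from [trace_ray()], the
#' effective buildup \eqn{B_{\mathrm{eff}}} from [effective_buildup()], and
#' \eqn{\kappa = 1.602\times10^{-13}\,\mathrm{J/MeV} \times 10^3\,\mathrm{g/kg}
#' \times 3600\,\mathrm{s/h}} (dose to water under the kerma approximation).
#'
#' @param built either a builder result (list with `geometry` and `sources`,
#'   see [build_brit_ldr()] and friends) or a [geometry()]; in the latter case
#'   supply `sources` too.
#' @param sources list of [encapsulated_source()] (ignored when `built` is a
#'   builder result).
#' @param delta_l emitter discretization step in cm (0.005 cm for
#'   reference-point work; grids default to a coarser 0.05 cm via
#'   [dose_rate_grid()]).
#' @param library physics library.
#' @param unit `"cGy/h"` or `"Gy/h"` for reported dose rates.
#' @return an object of class `dose_model`.
#' @export
dose_model <- function(built, sources = NULL, delta_l = 0.005,
                       library = standard_library(), unit = c("cGy/h", "Gy/h")) {
  unit <- match.arg(unit)
  if (inherits(built, "geometry")) {
    geom <- built
  } else {
    geom <- built$geometry
    sources <- built$sources
  }
  stopifnot(inherits(geom, "geometry"), length(sources) >= 1L)
  emit <- vector("list", length(sources))
  for (i in seq_along(sources)) {
    e <- discretize(sources[[i]], delta_l, library)
    e$source <- i
    emit[[i]] <- e
  }
  emitters <- do.call(rbind, emit)
  nuclides <- vapply(sources, `[[`, "", "nuclide")
  # every material a ray can traverse: the ambient, the region materials and
  # the packaged library (custom materials included by name)
  mats <- c(list(geom$ambient), lapply(geom$regions, `[[`, "material"),
            library$materials)
  mats <- mats[!duplicated(vapply(mats, `[[`, "", "name"))]
  names(mats) <- vapply(mats, `[[`, "", "name")
  # per-line physics caches, per source nuclide
  caches <- lapply(unique(nuclides), function(nuc) {
    sp <- library$spectra[[nuc]]
    if (is.null(sp)) stop("unknown nuclide '", nuc, "'")
    E <- sp$lines$E_MeV
    list(nuclide = nuc, E = E, yield = sp$lines$yield,
         mu_en_w = lookup_mu_en(library$absorbers$water, E),
         mu = lapply(mats, function(m) lookup_mu(m, E)))
  })
  names(caches) <- unique(nuclides)
  structure(list(geometry = geom, sources = sources, emitters = emitters,
                 nuclides = nuclides, caches = caches, library = library,
                 delta_l = delta_l, unit = unit,
                 applicator = if (!inherits(built, "geometry")) built$applicator else "custom",
                 params = if (!inherits(built, "geometry")) built$params else list()),
            class = "dose_model")
}

#' @export
print.dose_model <- function(x, ...) {
  cat(sprintf("<dose_model> %s: %d source(s), %d emitter(s) (delta_l = %g cm), %d region(s), unit %s\n",
              x$applicator, length(x$sources), nrow(x$emitters), x$delta_l,
              length(x$geometry$regions), x$unit))
  invisible(x)
}

#' @export
summary.dose_model <- function(object, ...) {
  acts <- vapply(seq_along(object$sources), function(i)
    sum(object$emitters$activity[object$emitters$source == i]), 0)
  df <- data.frame(source = vapply(object$sources, `[[`, "", "label"),
                   nuclide = object$nuclides,
                   activity_GBq = acts / 1e9)
  cat("Dose model:", object$applicator, "\n")
  print(df, row.names = FALSE)
  invisible(df)
}

.unit_scale <- function(unit) if (unit == "Gy/h") 0.01 else 1

# dose rate (cGy/h) at one point from a subset of emitters
.dose_point <- function(model, p, emitter_rows = seq_len(nrow(model$emitters))) {
  geom <- model$geometry
  em <- model$emitters[emitter_rows, , drop = FALSE]
  idx <- .classify_index(geom, matrix(p, ncol = 3))
  if (idx > 0L && geom$regions[[idx]]$is_source_core)
    stop(sprintf("dose point (%g, %g, %g) lies inside an active source pellet", p[1], p[2], p[3]))
  total <- 0
  for (r in seq_len(nrow(em))) {
    a <- c(em$x[r], em$y[r], em$z[r])
    d2 <- sum((p - a)^2)
    if (d2 < 1e-12)
      stop(sprintf("dose point (%g, %g, %g) coincides with a point emitter", p[1], p[2], p[3]))
    cache <- model$caches[[model$nuclides[em$source[r]]]]
    path <- trace_ray(geom, a, p)
    mat_names <- vapply(path$material, `[[`, "", "name")
    # optical thickness per spectrum line: (n_seg x n_E)
    mu_mat <- do.call(rbind, cache$mu[mat_names])
    lsum <- as.numeric(path$length %*% mu_mat)
    B <- vapply(seq_along(cache$E), function(i) {
      path$optical <- mu_mat[, i] * path$length
      effective_buildup(path, cache$E[i])
    }, 0)
    total <- total + em$activity[r] / (4 * pi * d2) *
      sum(cache$yield * cache$E * cache$mu_en_w * exp(-lsum) * B)
  }
  total * .DOSE_CONST
}

#' Dose rate at a point
#'
#' @param model a [dose_model()].
#' @param p 3-vector (cm) or n x 3 matrix of points.
#' @return dose rate(s) in the model's unit (cGy/h by default).
#' @export
dose_rate <- function(model, p) {
  s <- .unit_scale(model$unit)
  if (is.null(dim(p))) return(.dose_point(model, as.numeric(p)) * s)
  apply(p, 1, function(row) .dose_point(model, as.numeric(row))) * s
}

#' Predict method: dose rates at new points
#'
#' @param object a [dose_model()].
#' @param newdata data.frame with columns `x`, `y`, `z` (cm) or an n x 3 matrix.
#' @param ... unused.
#' @return numeric vector of dose rates.
#' @export
predict.dose_model <- function(object, newdata, ...) {
  pts <- if (is.data.frame(newdata)) as.matrix(newdata[, c("x", "y", "z")]) else as.matrix(newdata)
  dose_rate(object, pts)
}

#' Manchester reference points
#'
#' Convenience set: points A and B left/right in the applicator frame.
#'
#' @param extra optional named list of additional 3-vectors (e.g. bladder and
#'   rectum points, which are anatomy-dependent user inputs).
#' @return data.frame with columns `point`, `x`, `y`, `z`.
#' @export
reference_points <- function(extra = list()) {
  base <- data.frame(point = c("A_right", "A_left", "B_right", "B_left"),
                     x = c(2, -2, 5, -5), y = c(2, 2, 2, 2), z = 0)
  if (length(extra)) {
    if (is.null(names(extra)) || anyDuplicated(c(base$point, names(extra))))
      stop("extra reference points must have unique names")
    ex <- do.call(rbind, lapply(extra, function(v) data.frame(x = v[1], y = v[2], z = v[3])))
    ex <- cbind(point = names(extra), ex)
    base <- rbind(base, ex)
  }
  rownames(base) <- NULL
  base
}

#' Evaluate a plan at reference points
#'
#' @param model a [dose_model()].
#' @param points data.frame with columns `point`, `x`, `y`, `z` (see
#'   [reference_points()]); an empty data.frame yields an empty table.
#' @param per_source if `TRUE`, add one dose column per source plus the total.
#' @return data.frame with one row per point: `point`, `x`, `y`, `z`,
#'   `dose_rate` (and per-source columns if requested) and `unit`.
#' @export
evaluate_plan <- function(model, points = reference_points(), per_source = FALSE) {
  stopifnot(all(c("point", "x", "y", "z") %in% names(points)))
  s <- .unit_scale(model$unit)
  n <- nrow(points)
  out <- points
  if (per_source) {
    labs <- vapply(model$sources, `[[`, "", "label")
    for (j in seq_along(model$sources)) {
      rows <- which(model$emitters$source == j)
      out[[labs[j]]] <- if (n) vapply(seq_len(n), function(i)
        tryCatch(.dose_point(model, as.numeric(points[i, c("x", "y", "z")]), rows) * s,
                 error = function(e) stop("at point '", points$point[i], "': ",
                                          conditionMessage(e))), 0) else numeric(0)
    }
    out$dose_rate <- if (n) rowSums(out[, labs, drop = FALSE]) else numeric(0)
  } else {
    out$dose_rate <- if (n) vapply(seq_len(n), function(i)
      tryCatch(.dose_point(model, as.numeric(points[i, c("x", "y", "z")])) * s,
               error = function(e) stop("at point '", points$point[i], "': ",
                                        conditionMessage(e))), 0) else numeric(0)
  }
  out$unit <- rep(model$unit, n)
  out
}

#' Percent dose-rate reduction caused by applicator walls
#'
#' `100 * (1 - D_with / D_without)` at a point, for two models sharing
#' identical emitters (e.g. a walls-on and a sources-only build of the same
#' loading). May be negative if buildup outweighs attenuation.
#'
#' @param model_with_walls,model_sources_only two [dose_model()]s with
#'   identical emitter sets.
#' @param p evaluation point, 3-vector cm.
#' @return percent reduction.
#' @export
applicator_attenuation_ratio <- function(model_with_walls, model_sources_only, p) {
  if (nrow(model_with_walls$emitters) != nrow(model_sources_only$emitters) ||
      max(abs(as.matrix(model_with_walls$emitters[, c("x", "y", "z", "activity")]) -
              as.matrix(model_sources_only$emitters[, c("x", "y", "z", "activity")]))) > 1e-9)
    stop("the two models must share identical emitters")
  d_with <- .dose_point(model_with_walls, as.numeric(p))
  d_without <- .dose_point(model_sources_only, as.numeric(p))
  if (d_without == 0) stop("undefined ratio: sources-only dose rate is zero at this point")
  100 * (1 - d_with / d_without)
}

#' Compute a 3D dose-rate grid
#'
#' Node values equal [dose_rate()] at the node coordinates. Nodes inside an
#' active source pellet are masked `NA`. Grids default to a coarser emitter
#' discretization (`delta_l = 0.05` cm) than reference-point work; pass the
#' parent model's `delta_l` to override.
#'
#' @param model a [dose_model()].
#' @param origin grid corner (cm), 3-vector.
#' @param spacing node spacing (cm), scalar or 3-vector, `> 0`.
#' @param dims number of nodes per axis, 3 integers.
#' @param delta_l emitter step used for the grid (the model is re-discretized
#'   when this differs from the model's own step).
#' @return an object of class `dose_grid`: list with `origin`, `spacing`,
#'   `dims`, axis vectors `x`, `y`, `z`, `values` (3D array, model units) and
#'   `unit`.
#' @export
dose_rate_grid <- function(model, origin, spacing, dims, delta_l = 0.05) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  stopifnot(all(spacing > 0), length(dims) == 3, all(dims >= 1))
  if (abs(delta_l - model$delta_l) > 1e-12)
    model <- dose_model(list(geometry = model$geometry, sources = model$sources,
                             applicator = model$applicator, params = model$params),
                        delta_l = delta_l, library = model$library, unit = model$unit)
  xs <- origin[1] + spacing[1] * (seq_len(dims[1]) - 1)
  ys <- origin[2] + spacing[2] * (seq_len(dims[2]) - 1)
  zs <- origin[3] + spacing[3] * (seq_len(dims[3]) - 1)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  idx <- .classify_index(model$geometry, pts)
  core <- vapply(idx, function(i) i > 0L && model$geometry$regions[[i]]$is_source_core, TRUE)
  s <- .unit_scale(model$unit)
  vals <- rep(NA_real_, nrow(pts))
  for (i in which(!core))
    vals[i] <- tryCatch(.dose_point(model, pts[i, ]) * s,
                        error = function(e) {
                          # singular nodes (on an emitter / in a pellet) are
                          # masked; anything else propagates
                          if (grepl("coincides|active source pellet",
                                    conditionMessage(e))) NA_real_
                          else stop(e)
                        })
  structure(list(origin = origin, spacing = spacing, dims = as.integer(dims),
                 x = xs, y = ys, z = zs,
                 values = array(vals, dim = dims), unit = model$unit),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d nodes, spacing (%g, %g, %g) cm, %d masked, unit %s\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(is.na(x$values)), x$unit))
  invisible(x)
}

#' Angular dose-rate profile around a cylindrical applicator
#'
#' Dose rates in the transverse plane through the source centre, at the given
#' radii and azimuths. Azimuth 0 is the +z (unshielded reference) direction,
#' increasing toward +x. With `mirror = TRUE` the 180-360 degree half is
#' duplicated from the 0-180 half.
#'
#' @param model a [dose_model()] built from [build_vaginal_cylinder()] (or any
#'   model whose `params` carry `source_center` and `outer_radius`).
#' @param radii radial distances from the cylinder axis, cm; must not be
#'   smaller than the applicator outer radius.
#' @param angles azimuths in degrees.
#' @param mirror duplicate onto 360 - theta.
#' @return data.frame with columns `r_cm`, `theta_deg`, `dose_rate`, `unit`.
#' @export
angular_profile <- function(model, radii = seq(1.5, 11, by = 0.5),
                            angles = seq(0, 180, by = 5), mirror = FALSE) {
  ctr <- model$params$source_center
  rout <- model$params$outer_radius
  if (is.null(ctr) || is.null(rout))
    stop("model does not describe a cylindrical applicator")
  if (any(radii < rout))
    stop("radii must not lie inside the applicator (outer radius ", rout, " cm)")
  g <- expand.grid(r_cm = radii, theta_deg = angles)
  th <- g$theta_deg * pi / 180
  pts <- cbind(ctr[1] + g$r_cm * sin(th), ctr[2], ctr[3] + g$r_cm * cos(th))
  g$dose_rate <- dose_rate(model, pts)
  if (mirror) {
    dup <- g[g$theta_deg > 0 & g$theta_deg < 180, ]
    dup$theta_deg <- 360 - dup$theta_deg
    g <- rbind(g, dup)
    g <- g[order(g$r_cm, g$theta_deg), ]
    rownames(g) <- NULL
  }
  g$unit <- model$unit
  g
}

#' Plot a dose model
#'
#' Draws isodose contours of a transverse/coronal/sagittal slice through the
#' model (computed on the fly on a modest grid).
#'
#' @param x a [dose_model()].
#' @param plane `"coronal"` (x-y), `"sagittal"` (y-z) or `"transverse"` (x-z).
#' @param center window centre, 3-vector cm.
#' @param half_width half-extent of the plotted window, cm.
#' @param n nodes per axis.
#' @param levels contour levels in model units (defaults chosen from the data).
#' @param offset out-of-plane offset, cm.
#' @param delta_l emitter step for the plot grid.
#' @param ... passed to [graphics::contour()].
#' @export
plot.dose_model <- function(x, plane = c("coronal", "sagittal", "transverse"),
                            center = c(0, 2, 0), half_width = 5, n = 41,
                            levels = NULL, delta_l = 0.05, ...) {
  plane <- match.arg(plane)
  # in-plane axis indices (1=x, 2=y, 3=z) and axis labels
  ij <- switch(plane, coronal = c(1, 2), sagittal = c(2, 3), transverse = c(1, 3))
  labs <- c("x (cm)", "y (cm)", "z (cm)")
  origin <- center
  origin[ij] <- origin[ij] - half_width
  dims <- c(1, 1, 1); dims[ij] <- n
  spacing <- rep(2 * half_width / (n - 1), 3)
  g <- dose_rate_grid(x, origin, spacing, dims, delta_l = delta_l)
  u <- list(g$x, g$y, g$z)[[ij[1]]]
  v <- list(g$x, g$y, g$z)[[ij[2]]]
  zmat <- matrix(as.numeric(g$values), length(u), length(v))
  if (is.null(levels)) {
    q <- stats::quantile(zmat, c(0.5, 0.75, 0.9, 0.97), na.rm = TRUE)
    levels <- unique(signif(as.numeric(q), 2))
  }
  graphics::contour(u, v, zmat, levels = levels, xlab = labs[ij[1]],
                    ylab = labs[ij[2]], main = sprintf("%s isodose (%s)", plane, x$unit),
                    asp = 1, ...)
  invisible(g)
}
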