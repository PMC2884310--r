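#' Extract isodose contours from a dose grid
#'
#' Slices a [dose_rate_grid()] result along one axis and extracts planar
#' isodose polylines by marching squares with linear interpolation along cell
#' edges (via [grDevices::contourLines()]). Levels are either absolute (model
#' units) or percent of the dose rate at a normalization point.
#'
#' @param grid a `dose_grid`.
#' @param plane_axis `"x"`, `"y"` or `"z"`: the axis normal to the contour plane.
#' @param offset position of the plane along `plane_axis`, cm; the nearest
#'   grid plane is used (and must lie inside the grid).
#' @param levels contour levels: percent of the normalization dose when
#'   `normalize` is given, otherwise absolute dose rates in grid units.
#' @param normalize optional normalization: either a dose rate (model units)
#'   or a 3-vector point, which must lie inside the grid and is looked up by
#'   trilinear interpolation.
#' @return an object of class `isodose_set`: data.frame with columns `level`
#'   (requested level), `dose_rate` (absolute level in grid units), `plane`,
#'   `polyline`, `vertex`, `x`, `y`, `z`, plus attributes `normalization`
#'   and `unit`. Levels that intersect nothing contribute no rows.
#' @export
extract_contours <- function(grid, plane_axis = c("z", "x", "y"), offset = 0,
                             levels = c(100, 200), normalize = NULL) {
  plane_axis <- match.arg(plane_axis)
  stopifnot(inherits(grid, "dose_grid"), all(levels > 0))
  ax <- match(plane_axis, c("x", "y", "z"))
  coords <- list(grid$x, grid$y, grid$z)
  if (offset < min(coords[[ax]]) - grid$spacing[ax] / 2 ||
      offset > max(coords[[ax]]) + grid$spacing[ax] / 2)
    stop("plane ", plane_axis, " = ", offset, " does not intersect the grid")
  k <- which.min(abs(coords[[ax]] - offset))
  sl <- switch(plane_axis,
               x = grid$values[k, , ],
               y = grid$values[, k, ],
               z = grid$values[, , k])
  uv <- coords[-ax]
  sl <- matrix(sl, length(uv[[1]]), length(uv[[2]]))
  norm_dose <- NULL
  if (!is.null(normalize)) {
    norm_dose <- if (length(normalize) == 3) .grid_interp(grid, normalize) else as.numeric(normalize)
    if (!is.finite(norm_dose) || norm_dose <= 0)
      stop("invalid normalization dose rate")
    abs_levels <- levels / 100 * norm_dose
  } else abs_levels <- levels
  # contourLines rejects NA: fill masked nodes (source cores, far above any
  # clinically plotted level) with the finite grid maximum so contours of
  # lower levels are unaffected
  filled <- sl
  if (anyNA(filled)) filled[is.na(filled)] <- max(sl, na.rm = TRUE)
  rows <- list()
  for (i in seq_along(abs_levels)) {
    if (abs_levels[i] >= max(filled) || abs_levels[i] <= min(filled)) next
    cl <- grDevices::contourLines(uv[[1]], uv[[2]], filled, levels = abs_levels[i])
    for (j in seq_along(cl)) {
      nv <- length(cl[[j]]$x)
      pl <- data.frame(level = levels[i], dose_rate = abs_levels[i],
                       plane = sprintf("%s=%g", plane_axis, coords[[ax]][k]),
                       polyline = j, vertex = seq_len(nv))
      xyz <- matrix(0, nv, 3)
      xyz[, ax] <- coords[[ax]][k]
      xyz[, setdiff(1:3, ax)] <- cbind(cl[[j]]$x, cl[[j]]$y)
      pl$x <- xyz[, 1]; pl$y <- xyz[, 2]; pl$z <- xyz[, 3]
      rows[[length(rows) + 1L]] <- pl
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(level = numeric(0), dose_rate = numeric(0), plane = character(0),
               polyline = integer(0), vertex = integer(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  structure(out, normalization = norm_dose, unit = grid$unit,
            class = c("isodose_set", "data.frame"))
}

# trilinear interpolation of a dose grid at a point (NA nodes propagate)
.grid_interp <- function(grid, p) {
  f <- (as.numeric(p) - grid$origin) / grid$spacing
  i0 <- pmin(pmax(floor(f), 0), grid$dims - 2)
  i0[grid$dims == 1] <- 0
  w <- f - i0
  w[grid$dims == 1] <- 0
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ww <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
    if (ww == 0) next
    idx <- pmin(i0 + c(dx, dy, dz), grid$dims - 1) + 1
    val <- val + ww * grid$values[idx[1], idx[2], idx[3]]
  }
  val
}

#' Plot an isodose set
#'
#' @param x an `isodose_set` from [extract_contours()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.isodose_set <- function(x, ...) {
  if (!nrow(x)) { graphics::plot.new(); return(invisible(x)) }
  ax <- if (length(unique(x$x)) == 1) c("y", "z") else if (length(unique(x$y)) == 1)
    c("x", "z") else c("x", "y")
  u <- x[[ax[1]]]; v <- x[[ax[2]]]
  graphics::plot(range(u), range(v), type = "n",
                 xlab = paste0(ax[1], " (cm)"), ylab = paste0(ax[2], " (cm)"),
                 asp = 1, ...)
  lv <- sort(unique(x$level))
  for (i in seq_along(lv)) {
    sub <- x[x$level == lv[i], ]
    for (j in unique(sub$polyline))
      graphics::lines(sub[[ax[1]]][sub$polyline == j], sub[[ax[2]]][sub$polyline == j],
                      col = i, lwd = 2)
  }
  graphics::legend("topright", legend = lv, col = seq_along(lv), lwd = 2, bty = "n")
  invisible(x)
}

#' Write contours as delimited text
#'
#' Columns: level, dose_rate, plane, polyline, vertex, x, y, z.
#'
#' @param contours an `isodose_set`.
#' @param path output file.
#' @export
write_contours <- function(contours, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# isodose contours (%s)", attr(contours, "unit")),
               if (!is.null(attr(contours, "normalization")))
                 sprintf("# normalization_dose_rate: %.9g", attr(contours, "normalization"))),
             con)
  utils::write.table(as.data.frame(contours), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
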