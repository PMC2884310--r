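#' @name primitives
#' @title Solid primitives for applicator modeling
#'
#' @description Primitives are closed solids used to assemble material
#'   regions: finite cylinders, spheres, axis-aligned-free boxes and angular
#'   sector shells (partial cylindrical annuli, used for sector shields).
#'   Points are classified by containment; rays are intersected analytically.
#'
#' @param base 3-vector, cm: cylinder/sector base point (centre of the lower cap).
#' @param axis 3-vector: cylinder/sector axis (normalized internally).
#' @param radius radius in cm, `> 0`.
#' @param length axial extent in cm, `> 0`.
#' @param center sphere centre, cm.
#' @param corner box corner, cm.
#' @param edges 3x3 matrix whose rows are mutually orthogonal edge vectors, cm.
#' @param r_inner,r_outer inner/outer radii of a sector shell, cm.
#' @param angle_start,angle_stop azimuthal span in degrees, `0 <= start < stop <= 360`,
#'   measured from `ref` toward `cross(axis, ref)`.
#' @param ref 3-vector defining azimuth zero for a sector shell (projected
#'   perpendicular to `axis` and normalized).
#' @return a primitive object.
NULL

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

#' @rdname primitives
#' @export
prim_cylinder <- function(base, axis, radius, length) {
  stopifnot(radius > 0, length > 0)
  structure(list(kind = "cylinder", base = as.numeric(base), axis = .unit(axis),
                 radius = radius, length = length), class = "primitive")
}

#' @rdname primitives
#' @export
prim_sphere <- function(center, radius) {
  stopifnot(radius > 0)
  structure(list(kind = "sphere", center = as.numeric(center), radius = radius),
            class = "primitive")
}

#' @rdname primitives
#' @export
prim_box <- function(corner, edges) {
  edges <- as.matrix(edges)
  stopifnot(all(dim(edges) == c(3, 3)))
  structure(list(kind = "box", corner = as.numeric(corner), edges = edges,
                 len2 = rowSums(edges^2)), class = "primitive")
}

#' @rdname primitives
#' @export
prim_sector_shell <- function(base, axis, r_inner, r_outer, length,
                              angle_start, angle_stop, ref) {
  stopifnot(r_outer > r_inner, r_inner >= 0, length > 0,
            angle_start >= 0, angle_stop <= 360, angle_start < angle_stop)
  axis <- .unit(axis)
  ref <- as.numeric(ref)
  ref <- ref - sum(ref * axis) * axis
  structure(list(kind = "sector", base = as.numeric(base), axis = axis,
                 r_inner = r_inner, r_outer = r_outer, length = length,
                 a0 = angle_start, a1 = angle_stop,
                 u = .unit(ref), v = .unit(.cross(axis, ref))),
            class = "primitive")
}

.cross <- function(a, b) c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3], a[1]*b[2] - a[2]*b[1])

# containment test, vectorized over an n x 3 matrix of points
.prim_contains <- function(p, pts) {
  switch(p$kind,
    cylinder = {
      rel <- sweep(pts, 2, p$base)
      s <- rel %*% p$axis
      perp2 <- rowSums(rel^2) - s^2
      s >= 0 & s <= p$length & perp2 <= p$radius^2
    },
    sphere = {
      rel <- sweep(pts, 2, p$center)
      rowSums(rel^2) <= p$radius^2
    },
    box = {
      rel <- sweep(pts, 2, p$corner)
      u <- rel %*% t(p$edges)          # n x 3 of dot products
      ok <- u >= 0 & sweep(u, 2, p$len2, "<=")
      ok[, 1] & ok[, 2] & ok[, 3]
    },
    sector = {
      rel <- sweep(pts, 2, p$base)
      s <- rel %*% p$axis
      x <- rel %*% p$u
      y <- rel %*% p$v
      r2 <- x^2 + y^2
      phi <- (atan2(y, x) * 180 / pi) %% 360
      s >= 0 & s <= p$length & r2 >= p$r_inner^2 & r2 <= p$r_outer^2 &
        phi >= p$a0 & phi <= p$a1
    })
}

# parameters t in (0,1) where the segment a + t*(b-a) crosses any bounding
# surface of the primitive; superfluous candidates are harmless because the
# tracer classifies segment midpoints.
.prim_crossings <- function(p, a, d) {
  ts <- numeric(0)
  quad <- function(A, B, C) {
    if (abs(A) < 1e-300) {
      if (abs(B) > 1e-300) return(-C / B)
      return(numeric(0))
    }
    disc <- B * B - 4 * A * C
    if (disc <= 0) return(numeric(0))
    sq <- sqrt(disc)
    c((-B - sq) / (2 * A), (-B + sq) / (2 * A))
  }
  cyl_ts <- function(base, axis, radius, length) {
    rel <- a - base
    dd <- sum(d * axis); rr <- sum(rel * axis)
    dp <- d - dd * axis; rp <- rel - rr * axis
    out <- quad(sum(dp^2), 2 * sum(dp * rp), sum(rp^2) - radius^2)
    if (abs(dd) > 1e-300) out <- c(out, (0 - rr) / dd, (length - rr) / dd)
    out
  }
  switch(p$kind,
    cylinder = { ts <- cyl_ts(p$base, p$axis, p$radius, p$length) },
    sphere = {
      rel <- a - p$center
      ts <- quad(sum(d^2), 2 * sum(d * rel), sum(rel^2) - p$radius^2)
    },
    box = {
      rel <- a - p$corner
      for (i in 1:3) {
        e <- p$edges[i, ]
        de <- sum(d * e)
        if (abs(de) > 1e-300) {
          re <- sum(rel * e)
          ts <- c(ts, -re / de, (p$len2[i] - re) / de)
        }
      }
    },
    sector = {
      ts <- c(cyl_ts(p$base, p$axis, p$r_outer, p$length),
              if (p$r_inner > 0) cyl_ts(p$base, p$axis, p$r_inner, p$length))
      rel <- a - p$base
      for (ang in c(p$a0, p$a1)) {
        # plane through the axis containing the azimuth-ang direction
        n <- -sin(ang * pi / 180) * p$u + cos(ang * pi / 180) * p$v
        dn <- sum(d * n)
        if (abs(dn) > 1e-300) ts <- c(ts, -sum(rel * n) / dn)
      }
    })
  ts[ts > 1e-12 & ts < 1 - 1e-12]
}

#' Define a material region from primitives
#'
#' A region is the intersection of its `include` primitives minus the union
#' of its `exclude` primitives. Where regions overlap, the highest `priority`
#' wins; the ambient medium of the [geometry()] acts as an implicit
#' lowest-priority all-space region.
#'
#' @param material a [material()].
#' @param include list of primitives (or one primitive) whose intersection
#'   forms the region.
#' @param exclude optional list of primitives carved out of the region.
#' @param priority integer; higher values override lower ones.
#' @param is_source_core flag marking active source material, used to mask
#'   dose singularities.
#' @return an object of class `region`.
#' @export
region <- function(material, include, exclude = list(), priority = 0L,
                   is_source_core = FALSE) {
  if (inherits(include, "primitive")) include <- list(include)
  if (inherits(exclude, "primitive")) exclude <- list(exclude)
  stopifnot(inherits(material, "material"), length(include) >= 1L)
  structure(list(material = material, include = include, exclude = exclude,
                 priority = as.integer(priority), is_source_core = is_source_core),
            class = "region")
}

.region_contains <- function(r, pts) {
  inside <- rep(TRUE, nrow(pts))
  for (p in r$include) inside <- inside & .prim_contains(p, pts)
  for (p in r$exclude) inside <- inside & !.prim_contains(p, pts)
  inside
}

#' Assemble a geometry from regions and an ambient medium
#'
#' @param regions list of [region()] objects (may be empty).
#' @param ambient the ambient [material()] filling all space not claimed by a
#'   region (water for in-phantom dosimetry).
#' @return an object of class `geometry`.
#' @export
geometry <- function(regions = list(), ambient) {
  if (inherits(regions, "region")) regions <- list(regions)
  stopifnot(inherits(ambient, "material"))
  ord <- order(vapply(regions, `[[`, 0L, "priority"), decreasing = TRUE)
  structure(list(regions = regions[ord], ambient = ambient), class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d region(s), ambient = %s\n", length(x$regions), x$ambient$name))
  for (r in x$regions)
    cat(sprintf("  [%d] %-10s %d primitive(s)%s\n", r$priority, r$material$name,
                length(r$include) + length(r$exclude),
                if (r$is_source_core) " (source core)" else ""))
  invisible(x)
}

#' Classify points to materials
#'
#' Each point resolves to the material of the highest-priority containing
#' region, or the ambient material when no region contains it.
#'
#' @param geom a [geometry()].
#' @param pts 3-vector or n x 3 matrix of points (cm).
#' @return list of [material()] objects of length n (a single material if
#'   one point was supplied).
#' @export
classify <- function(geom, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  idx <- rep(0L, nrow(pts))          # 0 = ambient
  for (k in seq_along(geom$regions)) {
    open <- idx == 0L
    if (!any(open)) break
    hit <- .region_contains(geom$regions[[k]], pts[open, , drop = FALSE])
    idx[open][hit] <- k
  }
  out <- lapply(idx, function(i) if (i == 0L) geom$ambient else geom$regions[[i]]$material)
  if (length(out) == 1L) out[[1]] else out
}

# region index per point (0 = ambient); internal, used for core masking
.classify_index <- function(geom, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  idx <- rep(0L, nrow(pts))
  for (k in seq_along(geom$regions)) {
    open <- idx == 0L
    if (!any(open)) break
    hit <- .region_contains(geom$regions[[k]], pts[open, , drop = FALSE])
    idx[open][hit] <- k
  }
  idx
}

#' Trace a ray into per-material path segments
#'
#' Splits the segment from `a` to `b` at every material boundary and returns
#' the ordered per-material physical path lengths (source to detector).
#' Segment lengths sum to `|b - a|` exactly (the split parameters partition
#' `[0, 1]`); adjacent same-material segments are merged. Optical thicknesses
#' at a given energy are attached by the caller (see [path_optical()]).
#'
#' @param geom a [geometry()].
#' @param a,b endpoints in cm; `a != b`.
#' @return a `layer_path`: list with `material` (list of [material()]),
#'   `length` (cm) and `total` (`|b-a|`, cm).
#' @export
trace_ray <- function(geom, a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  d <- b - a
  L <- sqrt(sum(d^2))
  if (L < 1e-12) stop("degenerate ray: endpoints coincide")
  ts <- numeric(0)
  for (r in geom$regions) {
    for (p in r$include) ts <- c(ts, .prim_crossings(p, a, d))
    for (p in r$exclude) ts <- c(ts, .prim_crossings(p, a, d))
  }
  if (length(ts)) {
    ts <- sort(ts)
    ts <- ts[c(TRUE, diff(ts) > 1e-12)]
  }
  knots <- c(0, ts, 1)
  mid <- sweep(outer((knots[-1] + knots[-length(knots)]) / 2, d), 2, a, "+")
  mats <- classify(geom, mid)
  if (inherits(mats, "material")) mats <- list(mats)
  seglen <- diff(knots) * L
  nm <- vapply(mats, function(m) m$name, "")
  n <- length(nm)
  grp <- if (n > 1L) cumsum(c(TRUE, nm[-1] != nm[-n])) else 1L
  structure(list(material = mats[!duplicated(grp)],
                 length = as.numeric(tapply(seglen, grp, sum)),
                 total = L),
            class = "layer_path")
}

#' Attach optical thicknesses to a traced path
#'
#' @param path a `layer_path` from [trace_ray()].
#' @param E photon energy in MeV.
#' @return the path with an `optical` component (mfp per segment) added.
#' @export
path_optical <- function(path, E) {
  path$optical <- vapply(seq_along(path$length), function(i)
    path$length[i] * lookup_mu(path$material[[i]], E), 0)
  path
}
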