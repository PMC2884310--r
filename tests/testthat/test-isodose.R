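make_point_grid <- function(half = 2.5, spacing = 0.05) {
  m <- bare_point_model(1e9, ambient = vacuum_material())
  n <- round(2 * half / spacing) + 1
  g <- dose_rate_grid(m, origin = c(-half, -half, 0), spacing = spacing,
                      dims = c(n, n, 1), delta_l = m$delta_l)
  list(model = m, grid = g)
}

test_that("a constant field yields no contours at other levels", {
  g <- structure(list(origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      dims = c(5L, 5L, 1L), x = 0:4, y = 0:4, z = 0,
                      values = array(7, c(5, 5, 1)), unit = "cGy/h"),
                 class = "dose_grid")
  ct <- extract_contours(g, "z", 0, levels = 3)
  expect_equal(nrow(ct), 0)
})

test_that("the 50% isodose of a bare emitter is a circle of radius sqrt(2)", {
  pg <- make_point_grid()
  norm <- dose_rate(pg$model, c(1, 0, 0))
  ct <- extract_contours(pg$grid, "z", 0, levels = c(100, 50), normalize = norm)
  expect_setequal(unique(ct$level), c(100, 50))
  c50 <- ct[ct$level == 50, ]
  radii <- sqrt(c50$x^2 + c50$y^2)
  expect_lt(max(abs(radii - sqrt(2))), pg$grid$spacing[1])
  c100 <- ct[ct$level == 100, ]
  expect_lt(max(abs(sqrt(c100$x^2 + c100$y^2) - 1)), pg$grid$spacing[1])
})

test_that("higher isodose levels nest inside lower ones", {
  pg <- make_point_grid()
  norm <- dose_rate(pg$model, c(1, 0, 0))
  ct <- extract_contours(pg$grid, "z", 0, levels = c(50, 150), normalize = norm)
  hi <- ct[ct$level == 150, ]
  lo <- ct[ct$level == 50, ]
  expect_gt(nrow(hi), 0); expect_gt(nrow(lo), 0)
  lo1 <- lo[lo$polyline == lo$polyline[1], ]
  for (k in seq_len(nrow(hi)))
    expect_true(point_in_polygon(hi$x[k], hi$y[k], lo1$x, lo1$y))
})

test_that("contour vertices re-evaluate to their level within 5% at 1 mm spacing", {
  m <- bare_point_model(1e9)
  g <- dose_rate_grid(m, origin = c(0.5, -1, 0), spacing = 0.1,
                      dims = c(21, 21, 1), delta_l = m$delta_l)
  lvl <- dose_rate(m, c(1.5, 0, 0))
  ct <- extract_contours(g, "z", 0, levels = lvl)
  expect_gt(nrow(ct), 0)
  sub <- ct[seq(1, nrow(ct), length.out = min(12, nrow(ct))), ]
  for (k in seq_len(nrow(sub))) {
    d <- dose_rate(m, c(sub$x[k], sub$y[k], 0))
    expect_lt(abs(d / lvl - 1), 0.05)
  }
})

test_that("percent levels demand a valid normalization and plane must intersect", {
  pg <- make_point_grid(half = 1, spacing = 0.25)
  expect_error(extract_contours(pg$grid, "z", 5, levels = 50), "does not intersect")
  expect_error(extract_contours(pg$grid, "z", 0, levels = 50, normalize = -1),
               "invalid normalization")
  # normalization by in-grid point interpolation
  ct <- extract_contours(pg$grid, "z", 0, levels = 120,
                         normalize = c(0.75, 0, 0))
  expect_true(all(ct$level == 120))
})

test_that("applicator isodose contours close around the loading and nest", {
  brit <- dose_model(build_brit_ldr(walls = FALSE), delta_l = 0.1)
  g <- dose_rate_grid(brit, origin = c(-6, -5, 0), spacing = 0.4,
                      dims = c(31, 31, 1), delta_l = 0.1)
  normA <- dose_rate(brit, c(2, 2, 0))
  ct <- extract_contours(g, "z", 0, levels = c(100, 200), normalize = normA)
  expect_setequal(unique(ct$level), c(100, 200))
  # every 200% vertex lies inside some 100% contour
  lo <- ct[ct$level == 100, ]
  hi <- ct[ct$level == 200, ]
  for (k in seq(1, nrow(hi), length.out = min(10, nrow(hi)))) {
    k <- round(k)
    inside_any <- any(vapply(unique(lo$polyline), function(pl)
      point_in_polygon(hi$x[k], hi$y[k], lo$x[lo$polyline == pl],
                       lo$y[lo$polyline == pl]), TRUE))
    expect_true(inside_any)
  }
})
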