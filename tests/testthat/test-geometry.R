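test_that("classification resolves to the highest-priority region, ambient otherwise", {
  empty <- geometry(list(), lib$materials$water)
  expect_equal(classify(empty, c(3, -1, 2))$name, "water")

  vc <- build_vaginal_cylinder(180)
  # the steel source-guide tube wall (0.4 cm OD) around the air channel
  expect_equal(classify(vc$geometry, c(0.175, 2, 0))$name, "steel")
  expect_equal(classify(vc$geometry, c(0, 2, 0))$name, "air")
  # far lateral point: ambient water
  expect_equal(classify(vc$geometry, c(10, 2, 0))$name, "water")
  # inside the plastic shell wall
  expect_equal(classify(vc$geometry, c(1.25, 7, 0))$name, "plastic")
  # tungsten occupies exactly the stated sector: shadowed at azimuth 180 (-z),
  # open at azimuth 0 (+z), at the same radius
  y <- vc$params$source_center[2]
  expect_equal(classify(vc$geometry, c(0, y, -0.6))$name, "tungsten")
  expect_equal(classify(vc$geometry, c(0, y, +0.6))$name, "air")
  # 0 shield angle removes the tungsten region entirely
  vc0 <- build_vaginal_cylinder(0)
  expect_equal(classify(vc0$geometry, c(0, y, -0.6))$name, "air")
  expect_error(build_vaginal_cylinder(45), "must be one of")
})

test_that("ray tracing through a thin shell gives the chord lengths", {
  st <- lib$materials$steel
  shell <- geometry(list(
    region(st, prim_cylinder(c(0, -5, 0), c(0, 1, 0), 0.30, 10),
           exclude = prim_cylinder(c(0, -5, 0), c(0, 1, 0), 0.25, 10))),
    lib$materials$water)
  # perpendicular ray through the axis: 2 x 0.05 cm of steel
  tr <- trace_ray(shell, c(-2, 0, 0), c(2, 0, 0))
  nm <- vapply(tr$material, `[[`, "", "name")
  stl <- sum(tr$length[nm == "steel"])
  expect_equal(stl, 0.10, tolerance = 1e-9)
  expect_equal(sum(tr$length), 4, tolerance = 1e-9)
  # homogeneous medium: a single ambient segment
  tr <- trace_ray(shell, c(5, 0, 0), c(5, 5, 0))
  expect_equal(length(tr$length), 1)
  expect_equal(tr$material[[1]]$name, "water")
  expect_error(trace_ray(shell, c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("oblique slab crossings scale as 1/cos(angle), confirmed by point sampling", {
  st <- lib$materials$steel
  slab <- geometry(list(
    region(st, prim_box(c(-10, 0, -10),
                        edges = rbind(c(20, 0, 0), c(0, 0.2, 0), c(0, 0, 20))))),
    lib$materials$water)
  a <- c(-3, -2.9, 0); b <- c(3, 3.1, 0)   # 45 degrees to the slab normal
  tr <- trace_ray(slab, a, b)
  nm <- vapply(tr$material, `[[`, "", "name")
  stl <- sum(tr$length[nm == "steel"])
  expect_equal(stl, 0.2 * sqrt(2), tolerance = 1e-6)
  # dense-sampling oracle: occupancy fraction along the ray
  n <- 2e5
  t <- (seq_len(n) - 0.5) / n
  pts <- sweep(outer(t, b - a), 2, a, "+")
  mats <- classify(slab, pts)
  frac <- mean(vapply(mats, `[[`, "", "name") == "steel")
  expect_equal(stl, frac * sqrt(sum((b - a)^2)), tolerance = 1e-3)
})

test_that("traced segment lengths always partition the ray, in both directions", {
  set.seed(7)
  builds <- list(build_brit_ldr(walls = TRUE),
                 build_fletcher_green(),
                 build_fletcher_williamson(),
                 build_vaginal_cylinder(270))
  for (b in builds) {
    for (k in 1:200) {
      a <- runif(3, -8, 8); p <- runif(3, -8, 8)
      if (sum((a - p)^2) < 1e-6) next
      tr <- trace_ray(b$geometry, a, p)
      expect_equal(sum(tr$length), sqrt(sum((p - a)^2)), tolerance = 1e-9)
      rev <- trace_ray(b$geometry, p, a)
      expect_equal(rev$length, rev(tr$length), tolerance = 1e-9)
      expect_equal(vapply(rev$material, `[[`, "", "name"),
                   rev(vapply(tr$material, `[[`, "", "name")))
    }
  }
})

test_that("segment midpoints classify to their segment's material", {
  b <- build_brit_ldr(walls = TRUE)
  set.seed(11)
  for (k in 1:50) {
    a <- runif(3, -4, 7); p <- runif(3, -4, 7)
    if (sum((a - p)^2) < 1e-6) next
    tr <- trace_ray(b$geometry, a, p)
    s <- c(0, cumsum(tr$length))
    u <- (p - a) / sum(tr$length)
    for (i in seq_along(tr$length)) {
      mid <- a + (s[i] + tr$length[i] / 2) * u
      expect_equal(classify(b$geometry, mid)$name, tr$material[[i]]$name)
    }
  }
})

test_that("sector shell volume matches a Monte Carlo estimate", {
  sec <- prim_sector_shell(c(0, 0, 0), c(0, 1, 0), r_inner = 0.2, r_outer = 1.0,
                           length = 2, angle_start = 135, angle_stop = 225,
                           ref = c(0, 0, 1))
  analytic <- pi * (1.0^2 - 0.2^2) * 2 * (90 / 360)
  set.seed(3)
  n <- 2e5
  pts <- cbind(runif(n, -1, 1), runif(n, 0, 2), runif(n, -1, 1))
  inside <- brachydose:::.prim_contains(sec, pts)
  mc <- mean(inside) * 2 * 2 * 2
  expect_rel_equal(mc, analytic, 0.03)
})

test_that("BRIT builder places the documented loadings", {
  b <- build_brit_ldr(tandem = "long", walls = TRUE)
  expect_length(b$sources, 5)
  expect_equal(vapply(b$sources, function(s) s$strength$value, 0),
               c(350, 230, 230, 230, 230))
  # fundus source is the strongest and sits highest
  ys <- vapply(b$sources, function(s) s$center[2], 0)
  expect_equal(which.max(ys), 1L)
  m <- build_brit_ldr(tandem = "medium")
  expect_length(m$sources, 4)
  expect_equal(vapply(m$sources[1:2], function(s) s$strength$value, 0), c(350, 230))
  # sources-only model keeps identical source positions
  n <- build_brit_ldr(tandem = "long", walls = FALSE)
  expect_equal(lapply(n$sources, `[[`, "center"), lapply(b$sources, `[[`, "center"))
  expect_lt(length(n$geometry$regions), length(b$geometry$regions))
  expect_warning(build_brit_ldr(ovoid_separation_cm = 5), "outside the studied")
})

test_that("Fletcher builders follow their loadings", {
  fg <- build_fletcher_green()
  expect_length(fg$sources, 5)
  expect_equal(vapply(fg$sources, function(s) s$strength$value, 0),
               c(54.2, 36.2, 36.2, 36.15, 36.15))
  expect_true(all(vapply(fg$sources, function(s) s$capsule_material$name, "") == "ptfe_alloy"))
  fw <- build_fletcher_williamson()
  expect_length(fw$sources, 20)
  expect_equal(sum(grepl("^T", vapply(fw$sources, `[[`, "", "label"))), 14)
  expect_equal(sum(vapply(fw$sources, function(s) s$strength$value, 0)), 40700,
               tolerance = 1e-9)
})
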