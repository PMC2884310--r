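test_that("discretization segments the active core uniformly and conserves emission", {
  st <- lib$materials$steel
  src <- encapsulated_source("Cs-137", 1.0, 0.18, 0.3, 2.0, st,
                             center = c(0, 0, 0), axis = c(0, 1, 0),
                             strength = list(value = 1e9, unit = "Bq"))
  em <- discretize(src, 0.25)
  expect_equal(nrow(em), 4)
  expect_equal(sort(em$y), c(-0.375, -0.125, 0.125, 0.375))
  expect_equal(em$activity, rep(2.5e8, 4))

  # zero-length source: a single emitter at the active centre, full strength
  pt <- encapsulated_source("Cs-137", 0, 0.05, 0.1, 0.5, st,
                            c(1, 2, 3), c(0, 0, 1),
                            strength = list(value = 5e8, unit = "Bq"))
  em <- discretize(pt, 0.005)
  expect_equal(nrow(em), 1)
  expect_equal(c(em$x, em$y, em$z), c(1, 2, 3))
  expect_equal(em$activity, 5e8)

  # the CSA-1 geometry at the reference step: 300 emitters, exact conservation
  csa1 <- encapsulated_source("Cs-137", 1.5, 0.18, 0.3, 2.0, st,
                              c(0, 5, 0), c(0, 1, 0),
                              strength = list(value = 350, unit = "uGy_h_m2"))
  em <- discretize(csa1, 0.005)
  expect_equal(nrow(em), 300)
  expect_equal(sum(em$activity), strength_to_activity(csa1), tolerance = 1e-12)
})

test_that("air-kerma strength converts to an activity consistent with the printed pairing", {
  st <- lib$materials$steel
  csa1 <- encapsulated_source("Cs-137", 1.5, 0.18, 0.3, 2.0, st,
                              c(0, 0, 0), c(0, 1, 0),
                              strength = list(value = 350, unit = "uGy_h_m2"))
  # 350 uGy/h m2 pairs with 120 mCi (4.44 GBq) via the unfiltered constant
  mCi <- 350 / kerma_rate_constant("Cs-137", lib) / 3.7e7
  expect_lt(abs(mCi / 120 - 1), 0.05)
  # the capsule-filtered conversion differs from the bare constant by only
  # the thin-steel transmission (a few per cent)
  expect_lt(abs(strength_to_activity(csa1) * kerma_rate_constant("Cs-137", lib) / 350 - 1),
            0.05)
  # zero strength -> zero activity
  z <- csa1; z$strength$value <- 0
  expect_identical(strength_to_activity(z), 0)
  # linear reference air-kerma rate scales over the nominal capsule length
  lin <- csa1; lin$strength <- list(value = 36.2, unit = "uGy_h_m2_per_cm")
  eq <- csa1; eq$strength <- list(value = 36.2 * 2.0, unit = "uGy_h_m2")
  expect_equal(strength_to_activity(lin), strength_to_activity(eq),
               tolerance = 1e-12)
})

test_that("a vendor activity disagreeing with the air-kerma strength warns", {
  st <- lib$materials$steel
  src <- encapsulated_source("Cs-137", 1.0, 0.18, 0.3, 2.0, st,
                             c(0, 0, 0), c(0, 1, 0),
                             strength = list(value = 350, unit = "uGy_h_m2",
                                             activity_Bq = 9e9))
  expect_warning(strength_to_activity(src), "disagrees")
})

test_that("discretized line source converges to its point-source far field", {
  st <- lib$materials$steel
  line <- encapsulated_source("Cs-137", 1.5, 0.18, 0.3, 2.0, st,
                              c(0, 0, 0), c(0, 1, 0),
                              strength = list(value = 1e9, unit = "Bq"))
  point <- encapsulated_source("Cs-137", 0, 0.18, 0.3, 0.5, st,
                               c(0, 0, 0), c(0, 1, 0),
                               strength = list(value = 1e9, unit = "Bq"))
  vac <- vacuum_material()
  m_line <- dose_model(geometry(list(), vac), sources = list(line))
  m_point <- dose_model(geometry(list(), vac), sources = list(point))
  p <- c(15, 0, 0)  # perpendicular bisector, r = 10x active length
  expect_rel_equal(dose_rate(m_line, p), dose_rate(m_point, p), 0.005)
})

test_that("near-field dose is Cauchy-convergent under refinement of delta_l", {
  st <- lib$materials$steel
  src <- function() encapsulated_source("Cs-137", 1.5, 0.18, 0.3, 2.0, st,
                                        c(0, 0, 0), c(0, 1, 0),
                                        strength = list(value = 1e9, unit = "Bq"))
  vac <- vacuum_material()
  d_at <- function(dl) dose_rate(dose_model(geometry(list(), vac),
                                            sources = list(src()), delta_l = dl),
                                 c(1, 0, 0))
  d <- vapply(c(0.2, 0.1, 0.05, 0.025), d_at, 0)
  ch <- abs(diff(d))
  expect_true(all(diff(ch) < 0))
})
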