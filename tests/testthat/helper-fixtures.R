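# Shared fixtures built in code at test time.

lib <- standard_library()

# an effectively non-interacting medium: mu so small that exp(-mu*d) == 1 in
# double precision over any centimetre-scale path, with unit buildup (b = 1)
vacuum_material <- function() {
  E <- c(0.01, 15)
  material("vacuum", density = 1e-12, effective_Z = 1,
           E = E, mu = rep(1e-30, 2),
           compton = rep(1, 2),
           gp = data.frame(b = c(1, 1), c = c(1, 1), a = c(0, 0),
                           xK = c(10, 10), d = c(0, 0)))
}

# bare Cs-137 point emitter of given activity: no capsule regions in the
# geometry, ambient as requested
bare_point_model <- function(activity_Bq = 1e9, ambient = lib$materials$water,
                             center = c(0, 0, 0), unit = "cGy/h") {
  src <- encapsulated_source("Cs-137", 0, 0.05, 0.1, 0.5, lib$materials$steel,
                             center, c(0, 1, 0),
                             strength = list(value = activity_Bq, unit = "Bq"))
  dose_model(geometry(list(), ambient), sources = list(src), unit = unit)
}

# ray-casting point-in-polygon (polygon as x/y vectors, implicitly closed)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
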