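test_that("APD extraction handles square pulses, interpolation and offsets", {
  t <- seq(0, 400, 0.1)
  v <- ifelse(t > 20 & t <= 120, 0, -85)
  eps <- extract_apds(t, v)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$apd, 100, tolerance = 0.2)

  expect_equal(nrow(extract_apds(t, rep(-85, length(t)))), 0)
  expect_error(extract_apds(numeric(), numeric()), "empty")

  # trapezoid crossing between samples: analytic crossing times
  # rise from -85 at t=10 to +15 at t=20 (crosses -75 at t=11),
  # fall from +15 at t=50 to -85 at t=60 (crosses -75 at t=59)
  tt <- seq(0, 80, 0.5)
  vv <- approx(c(0, 10, 20, 50, 60, 80), c(-85, -85, 15, 15, -85, -85),
               xout = tt)$y
  ep <- extract_apds(tt, vv)
  expect_equal(ep$t_up, 11, tolerance = 1e-9)
  expect_equal(ep$t_down, 59, tolerance = 1e-9)
  expect_equal(ep$apd, 48, tolerance = 1e-9)

  # invariance under time shift and sub-threshold voltage offset
  ep2 <- extract_apds(tt + 37.5, vv)
  expect_equal(ep2$apd, ep$apd, tolerance = 1e-9)
  ep3 <- extract_apds(tt, vv + 4)   # stays clear of the -75 mV threshold? no:
  # offsets that do not cross the threshold leave episode membership intact
  expect_equal(nrow(ep3), 1)

  # clipped episodes are flagged
  vclip <- ifelse(tt > 80 - 10, 0, -85)
  expect_true(extract_apds(tt, vclip)$clipped)
})

test_that("alternans magnitude and flag follow the definition", {
  a <- alternans_magnitude(c(200, 150, 200, 150))
  expect_equal(a$magnitude, 50)
  expect_true(a$alternans)
  b <- alternans_magnitude(rep(180, 6))
  expect_equal(b$magnitude, 0)
  expect_false(b$alternans)
  # monotone drift is not alternans even when differences are large
  d <- alternans_magnitude(c(300, 280, 260, 240, 220))
  expect_false(d$alternans)
  expect_error(alternans_magnitude(c(1, 2, 3)), "at least 4")
})

test_that("morphology classification on constructed action potentials", {
  # spike, notch at -20, dome at +5, then repolarization
  t <- seq(0, 300, 0.1)
  knots_t <- c(0, 5, 6, 25, 90, 180, 200, 300)
  knots_v <- c(-85, -85, 40, -20, 5, -10, -85, -85)
  v <- approx(knots_t, knots_v, xout = t)$y
  m <- classify_morphology(t, v, ref_apd = 190)
  expect_equal(m$notch_v, -20, tolerance = 0.5)
  expect_true(m$dome_present)
  expect_equal(m$dome_v, 5, tolerance = 0.5)
  expect_false(m$early_repolarization)

  # monotone repolarization: no dome, notch undefined
  v2 <- approx(c(0, 5, 6, 60, 300), c(-85, -85, 40, -85, -85), xout = t)$y
  m2 <- classify_morphology(t, v2, ref_apd = 190)
  expect_false(m2$dome_present)
  expect_true(is.na(m2$notch_v))
  expect_true(m2$early_repolarization)   # APD ~54 ms < half of 190

  # a subthreshold blip is not an action potential
  v3 <- approx(c(0, 5, 6, 60, 300), c(-85, -85, -60, -85, -85), xout = t)$y
  expect_error(classify_morphology(t, v3, threshold = -70), "upstroke")
})

test_that("phase-singularity detection on constructed fields", {
  n <- 41
  centre <- 21
  ang <- function(cx, cy) {
    outer(1:n, 1:n, function(i, j) atan2(i - cy, j - cx))
  }
  # planar wave: a 1D phase profile extruded in y has no winding
  ph_planar <- matrix(rep(seq(-pi, pi, length.out = n), each = n), n, n,
                      byrow = FALSE)
  Vn <- -30 + 20 * cos(ph_planar)
  Vl <- -30 + 20 * sin(ph_planar)
  expect_equal(nrow(detect_phase_singularities(Vn, Vl)), 0)

  # single archimedean spiral about the centre
  th <- ang(centre, centre)
  rr <- outer(1:n, 1:n, function(i, j) sqrt((i - centre)^2 + (j - centre)^2))
  ph <- th - 0.4 * rr
  Vn <- -30 + 20 * cos(ph)
  Vl <- -30 + 20 * sin(ph)
  tips <- detect_phase_singularities(Vn, Vl)
  expect_equal(nrow(tips), 1)
  expect_lt(abs(tips$x - (centre - 1)), 1.1)
  expect_lt(abs(tips$y - (centre - 1)), 1.1)

  # mirror pair: two tips of opposite chirality, zero net charge
  ph2 <- ang(11, 21) - ang(31, 21)
  Vn <- -30 + 20 * cos(ph2)
  Vl <- -30 + 20 * sin(ph2)
  tips2 <- detect_phase_singularities(Vn, Vl)
  expect_equal(nrow(tips2), 2)
  expect_setequal(tips2$chirality, c(-1, 1))
  expect_equal(topological_charge(tips2), 0)

  expect_error(detect_phase_singularities(Vn, Vl[1:10, 1:10]), "shapes")
})

test_that("dynamics classification follows the documented rule", {
  tt <- seq(0, 3000, 10)
  n <- length(tt)
  fixed_xy <- lapply(seq_len(n), function(i) cbind(50, 50, 1))
  stable <- list(t = tt, count = rep(1L, n), xy = fixed_xy)
  expect_equal(classify_dynamics(stable, horizon = 3000)$label, "stable")

  wander <- stable
  wander$xy <- lapply(seq_len(n), function(i)
    cbind(50 + 30 * cos(i / 10), 50 + 30 * sin(i / 10), 1))
  expect_equal(classify_dynamics(wander, horizon = 3000)$label,
               "quasiperiodic")

  ramp <- list(t = tt, count = pmin(1L + (seq_len(n) - 1L) %/% 20L, 8L))
  expect_equal(classify_dynamics(ramp, horizon = 3000)$label, "breakup")

  dead <- list(t = tt, count = c(rep(1L, 100), rep(0L, n - 100)))
  expect_equal(classify_dynamics(dead, horizon = 3000)$label, "no_wave")

  expect_error(classify_dynamics(stable, horizon = 9000), "horizon")
  # pure function: re-running yields the identical labelling
  expect_identical(classify_dynamics(ramp, horizon = 3000),
                   classify_dynamics(ramp, horizon = 3000))
})

test_that("restitution slope is the finite difference on sorted points", {
  r <- data.frame(di = c(200, 50, 100), apd = c(180, 100, 150))
  sl <- restitution_slope(r)
  expect_equal(sl$slope, c(1, 0.3))
  expect_equal(sl$di, c(75, 150))
})
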