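test_that("a uniform unstimulated sheet follows the single-cell trajectory", {
  s <- shared("rest", resting_state())
  f <- tissue_field(6, 6, step_cell(s, Istim = 60))  # kick every site equally
  sc <- step_cell(s, Istim = 60)
  for (i in 1:60) {
    f <- step_tissue(f)
    sc <- step_cell(sc)
  }
  expect_lt(max(abs(f$V - sc[["V"]])), 1e-9)
  expect_lt(diff(range(f$V)), 1e-12)   # stays spatially uniform
  expect_lt(max(abs(f$Cai - sc[["Cai"]])), 1e-12)
})

test_that("no-flux diffusion conserves the spatial mean", {
  set.seed(7)
  f <- tissue_field(24, 16, cell_state())
  f$V <- matrix(runif(24 * 16, -90, 20), 16, 24)
  m0 <- mean(f$V)
  for (i in 1:50) {
    f <- step_tissue(f, diffusion_only = TRUE)
    expect_lt(abs(mean(f$V) - m0), 1e-10)
  }
})

test_that("diffusion of a point release matches the 2D heat kernel", {
  n <- 61
  f <- tissue_field(n, n, cell_state(V = 0))
  f$V <- matrix(0, n, n)
  f$V[31, 31] <- 1000
  t_end <- 4
  nstep <- round(t_end / 0.01)
  for (i in seq_len(nstep)) f <- step_tissue(f, diffusion_only = TRUE)
  D <- f$D; dx <- f$dx
  amp <- 1000 * dx^2 / (4 * pi * D * t_end)
  err <- c()
  for (di in -8:8) for (dj in -8:8) {
    r2 <- (di^2 + dj^2) * dx^2
    pred <- amp * exp(-r2 / (4 * D * t_end))
    got <- f$V[31 + di, 31 + dj]
    if (pred > amp * 0.01) err <- c(err, abs(got - pred) / pred)
  }
  expect_lt(max(err), 0.01)
})

test_that("the explicit stability bound is enforced", {
  f <- tissue_field(8, 8)
  expect_error(step_tissue(f, dt = 0.05), "stability")
  expect_error(measure_cv(dt = 0.05, state = cell_state()), "stability")
})

test_that("cable conduction velocity is near 0.55 m/s and scales as sqrt(D)", {
  cv1 <- shared("cv_base", measure_cv(state = prepaced_state()))
  expect_gt(cv1$cv_m_s, 0.45)
  expect_lt(cv1$cv_m_s, 0.65)
  cv4 <- measure_cv(D = 0.001 / 4, state = prepaced_state(), t_max = 250)
  expect_equal(cv4$cv_m_s / cv1$cv_m_s, 0.5, tolerance = 0.1)
})

test_that("an inexcitable cable reports propagation failure", {
  p0 <- model_params(GNa = 0)
  expect_error(measure_cv(p0, state = cell_state(params = p0), t_max = 60),
               "propagation failure")
})

test_that("a planar wave in 2D travels at the 1D cable speed", {
  st <- prepaced_state()
  cv1 <- shared("cv_base", measure_cv(state = st))$cv_m_s
  r <- cw_tissue_run(as.numeric(st), 240L, 16L, 0.0125, 0.001,
                     model_params(), 0.01, 70, 5L, 120, 1,
                     FALSE, -55, -30, 2, 2000, 10, 2, -30,
                     matrix(c(-1, -1, 1), 1, 3), 0,
                     as.integer(c(8 + 16 * 99, 8 + 16 * 179)), 0.05,
                     numeric(), 16L)
  up <- function(v) {
    i <- which(v[-1] > -40 & v[-length(v)] <= -40)[1]
    r$trace_t[i] + (-40 - v[i]) / (v[i + 1] - v[i]) * 0.05
  }
  t1 <- up(r$traces[, 1]); t2 <- up(r$traces[, 2])
  cv2 <- 80 * 0.0125 / (t2 - t1) * 10
  expect_equal(cv2 / cv1, 1, tolerance = 0.02)
})

test_that("identical configurations reproduce a 2D run bitwise", {
  p <- model_params(Gsi = 0.03, kd = 0.3, kf = 0.3)
  st <- shared("prepaced_2000_tau03",
               prepace_cell(p, pacing_protocol(pcl = 2000, n_beats = 10)))
  go <- function() run_spiral(p, nx = 48, ny = 48, state = st, horizon = 60,
                              dt = 0.02, ecg_dt = 1, frame_dt = 10)
  a <- go(); b <- go()
  expect_identical(a$V_final, b$V_final)
  expect_identical(a$ecg_raw, b$ecg_raw)
  expect_identical(a$tips, b$tips)
})

test_that("snapshot series persist and restore losslessly", {
  s <- list(t = c(1, 2), V = list(matrix(rnorm(16), 4), matrix(rnorm(16), 4)),
            params = unclass(model_params()))
  f <- tempfile(fileext = ".rds")
  write_snapshots(s, f)
  expect_identical(read_snapshots(f), s)
})
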