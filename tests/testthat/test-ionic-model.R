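test_that("gate kinetics match the independent rate transcriptions", {
  Vs <- c(-90, -80, -60, -41, -40, -39, -20, 0, 20, 40)
  for (g in c("m", "h", "j", "d", "f", "x")) {
    for (V in Vs) {
      got <- gate_kinetics(g, V)
      want <- oracle_rates(g, V)
      expect_equal(got$y_inf, want$y_inf, tolerance = 1e-12)
      expect_equal(got$tau_y, want$tau_y, tolerance = 1e-12)
    }
  }
  for (g in c("xtof", "ytof")) {
    for (V in Vs) {
      got <- gate_kinetics(g, V)
      want <- oracle_ito_rates(g, V)
      expect_equal(got$y_inf, want$y_inf, tolerance = 1e-12)
      expect_equal(got$tau_y, want$tau_y, tolerance = 1e-12)
    }
  }
})

test_that("tau scaling multiplies only the calcium gate time constants", {
  p3 <- model_params(kd = 0.3, kf = 0.4)
  for (V in c(-80, -40, 0, 40)) {
    base <- lapply(c("m", "h", "j", "d", "f", "x", "xtof", "ytof"),
                   gate_kinetics, V = V)
    scal <- lapply(c("m", "h", "j", "d", "f", "x", "xtof", "ytof"),
                   gate_kinetics, V = V, params = p3)
    for (k in seq_along(base)) {
      expect_equal(scal[[k]]$y_inf, base[[k]]$y_inf)  # y_inf never scaled
      fac <- c(1, 1, 1, 0.3, 0.4, 1, 1, 1)[k]
      expect_equal(scal[[k]]$tau_y, fac * base[[k]]$tau_y, tolerance = 1e-12)
    }
  }
})

test_that("gate_kinetics rejects unknown gates and non-finite voltage", {
  expect_error(gate_kinetics("q", -80), "unknown gate_id")
  expect_error(gate_kinetics("m", NaN), "finite")
  expect_error(gate_kinetics("m", Inf), "finite")
})

test_that("clamped-voltage gate relaxation follows the closed-form exponential", {
  # Rush-Larsen stepping at fixed V must reproduce
  # y(t) = y_inf + (y0 - y_inf) exp(-t / tau) essentially exactly, and a
  # fine-step Euler integration must agree as an independent scheme
  dt <- 0.01
  for (g in c("m", "h", "j", "d", "f", "x", "xtof", "ytof")) {
    for (V in c(-80, -40, 0, 40)) {
      k <- gate_kinetics(g, V)
      y0 <- 0.2
      t_end <- 3 * min(k$tau_y, 12)
      n <- max(10, round(t_end / dt))
      y <- y0
      for (i in seq_len(n)) y <- k$y_inf + (y - k$y_inf) * exp(-dt / k$tau_y)
      closed <- k$y_inf + (y0 - k$y_inf) * exp(-n * dt / k$tau_y)
      expect_equal(y, closed, tolerance = 1e-6)

      h <- min(dt, k$tau_y / 50)
      m <- round(n * dt / h)
      ye <- y0
      for (i in seq_len(m)) ye <- ye + h * (k$y_inf - ye) / k$tau_y
      expect_equal(ye, closed, tolerance = 2e-2)
    }
  }
})

test_that("current breakdown matches the dual R transcription", {
  set.seed(11)
  p <- model_params(Gtof = 0.3, Gsi = 0.05)
  for (i in 1:20) {
    s <- cell_state(V = runif(1, -90, 40),
                    m = runif(1), h = runif(1), j = runif(1), d = runif(1),
                    f = runif(1), x = runif(1), xtof = runif(1),
                    ytof = runif(1), Cai = 10^runif(1, -5, -2), params = p)
    got <- total_current(s, p)
    want <- oracle_currents(s, p)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
    expect_equal(got$Iion,
                 with(want, INa + ISi + IK + IK1 + IKp + Ib + Itof),
                 tolerance = 1e-10)
  }
})

test_that("Ito vanishes at zero conductance and at its reversal potential", {
  p0 <- model_params(Gtof = 0)
  s <- cell_state(V = 10, Cai = 1e-3, params = p0)
  b0 <- total_current(s, p0)
  expect_identical(b0$Itof, 0)
  # with Gtof = 0 the breakdown equals the Ito-free LR1 cell exactly
  b_base <- oracle_currents(s, p0)
  expect_equal(b0$Iion, with(b_base, INa + ISi + IK + IK1 + IKp + Ib),
               tolerance = 1e-12)

  p1 <- model_params(Gtof = 0.5)
  s_rev <- cell_state(V = p1$Etof, xtof = 0.7, ytof = 0.6, Cai = 1e-3,
                      params = p1)
  expect_equal(total_current(s_rev, p1)$Itof, 0)
})

test_that("total_current rejects non-positive calcium", {
  s <- as.numeric(cell_state())
  s[10] <- -1e-5
  expect_error(cw_currents(s, model_params()), "Cai")
})

test_that("the resting state is a fixed point of the stepper", {
  s <- shared("rest", resting_state())
  expect_gt(s[["V"]], -90)
  expect_lt(s[["V"]], -80)
  s2 <- step_cell(s, Istim = 0)
  expect_lt(max(abs(as.numeric(s2) - as.numeric(s))), 1e-9)
  # gates sit at their steady state
  kin <- vapply(c("m", "h", "j", "d", "f", "x", "xtof", "ytof"),
                function(g) gate_kinetics(g, s[["V"]])$y_inf, numeric(1))
  expect_equal(unname(as.numeric(s)[2:9]), unname(kin), tolerance = 1e-9)
})

test_that("a suprathreshold stimulus elicits an action potential", {
  s <- shared("rest", resting_state())
  tr <- simulate_cell(s, duration = 450, stim_onsets = 2,
                      stim_amplitude = 60)
  up <- tr$trace[tr$trace$t_ms <= 7, ]
  expect_gt(max(up$V_mV), 0)                       # upstroke within 5 ms
  expect_lt(tr$trace$V_mV[nrow(tr$trace)], -75)    # repolarized
  # and the same result holds at half the time step (qualitative oracle)
  tr2 <- simulate_cell(s, duration = 450, stim_onsets = 2,
                       stim_amplitude = 60, dt = 0.005)
  expect_gt(max(tr2$trace$V_mV[tr2$trace$t_ms <= 7]), 0)
})

test_that("halving dt changes the APD by less than 1 ms", {
  s <- prepaced_state()
  apd_at <- function(dt) {
    tr <- simulate_cell(s, duration = 480, stim_onsets = 2,
                        stim_amplitude = 60, dt = dt, record_dt = dt)
    eps <- extract_apds(tr$trace$t_ms, tr$trace$V_mV)
    eps$apd[!eps$clipped][1]
  }
  a1 <- apd_at(0.01)
  a2 <- apd_at(0.005)
  expect_lt(abs(a1 - a2), 1)
})

test_that("gates remain boxed in [0,1] through a full action potential", {
  s <- shared("rest", resting_state())
  for (i in 1:400) {
    s <- step_cell(s, Istim = if (i <= 100) 60 else 0, dt = 0.01)
    g <- as.numeric(s)[2:9]
    expect_true(all(g >= 0 & g <= 1))
  }
})

test_that("cell simulation with tables agrees with the exact-rate path", {
  s <- prepaced_state()
  tr_tab <- simulate_cell(s, duration = 420, stim_onsets = 2,
                          stim_amplitude = 60)
  tr_ex <- simulate_cell(s, duration = 420, stim_onsets = 2,
                         stim_amplitude = 60, exact = TRUE)
  a1 <- extract_apds(tr_tab$trace$t_ms, tr_tab$trace$V_mV)
  a2 <- extract_apds(tr_ex$trace$t_ms, tr_ex$trace$V_mV)
  expect_lt(abs(a1$apd[1] - a2$apd[1]), 0.5)
  expect_lt(max(abs(tr_tab$trace$V_mV - tr_ex$trace$V_mV)), 1)
})
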