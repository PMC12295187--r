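test_that("pseudo-ECG basics: uniform field, antisymmetry, probe validation", {
  V <- matrix(-80, 12, 12)
  expect_equal(ecg_sample(V, c(0.05, 0.05, 1)), 0, tolerance = 1e-14)
  # bipolar with coincident partners is identically zero
  p <- c(0.03, 0.07, 0.8)
  expect_identical(ecg_sample(matrix(rnorm(144), 12), list(p, p)), 0)
  expect_error(ecg_sample(V, c(0.0125 * 3, 0.0125 * 5, 0)), "lattice site")
})

test_that("pseudo-ECG matches a brute-force evaluation of the integral", {
  set.seed(3)
  dx <- 0.0125
  V <- outer(1:8, 1:8, function(i, j) 3 * j - 2 * i)  # linear ramp
  probe <- c(0.2, -0.1, 0.4)
  expect_equal(ecg_sample(V, probe, dx), oracle_ecg(V, dx, probe),
               tolerance = 1e-12)
  Vr <- matrix(rnorm(64, sd = 30), 8, 8)
  expect_equal(ecg_sample(Vr, probe, dx), oracle_ecg(Vr, dx, probe),
               tolerance = 1e-12)
})

test_that("pseudo-ECG is linear in the voltage field", {
  set.seed(4)
  dx <- 0.0125
  V1 <- matrix(rnorm(100), 10)
  V2 <- matrix(rnorm(100), 10)
  probe <- c(0.06, 0.06, 0.5)
  expect_equal(ecg_sample(2.5 * V1 - 1.3 * V2, probe, dx),
               2.5 * ecg_sample(V1, probe, dx) -
                 1.3 * ecg_sample(V2, probe, dx),
               tolerance = 1e-10)
})

test_that("probe elevation monotonically attenuates a dipolar field", {
  n <- 32
  dx <- 0.0125
  V <- outer(1:n, 1:n, function(i, j) ifelse(j <= n / 2, 20, -80))
  centre <- (n - 1) * dx / 2
  mags <- vapply(c(0.5, 1, 2, 4), function(h)
    abs(ecg_sample(V, c(centre, centre, h), dx)), numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("ecg_trace produces one column per lead with irregularity scores", {
  set.seed(5)
  fields <- lapply(1:40, function(k)
    matrix(-60 + 30 * sin(k / 4) + rnorm(64, sd = 0.1), 8, 8))
  series <- list(t = seq_len(40), V = fields)
  tr <- ecg_trace(series, default_probes(8, 8))
  expect_s3_class(tr, "cw_ecg")
  expect_named(tr, c("t_ms", "ecg1_right", "ecg2_top", "ecg3_above", "ecg4"))
  expect_equal(nrow(tr), 40)
  irr <- attr(tr, "irregularity")
  expect_length(irr, 4)
  expect_true(all(is.finite(irr)))
  # degenerate but valid: single-frame series
  tr1 <- ecg_trace(list(t = 0, V = fields[1]), default_probes(8, 8))
  expect_equal(nrow(tr1), 1)
  expect_error(ecg_trace(list(t = numeric(), V = list()),
                         default_probes(8, 8)), "empty")
})

test_that("irregularity scores separate periodic from aperiodic traces", {
  set.seed(6)
  t <- seq(0, 60, 0.05)
  periodic <- sin(2 * pi * t / 3)
  aperiodic <- rnorm(length(t))
  expect_gt(dominant_power_fraction(periodic), 0.5)
  expect_lt(dominant_power_fraction(aperiodic), 0.2)
  expect_gt(sample_entropy(aperiodic), 2 * sample_entropy(periodic))
})
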