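# Independent scalar transcriptions of the rate functions and currents used
# as dual-implementation oracles.  Deliberately written in plain R, straight
# from the published formulas, sharing no code with the package internals.

oracle_rates <- function(gate, V, kd = 1, kf = 1) {
  ab <- switch(gate,
    m = {
      dv <- V + 47.13
      a <- if (abs(dv) < 1e-7) 3.2 else 0.32 * dv / (1 - exp(-0.1 * dv))
      c(a, 0.08 * exp(-V / 11))
    },
    h = if (V >= -40) c(0, 1 / (0.13 * (1 + exp((V + 10.66) / -11.1))))
        else c(0.135 * exp((80 + V) / -6.8),
               3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)),
    j = if (V >= -40) c(0, 0.3 * exp(-2.535e-7 * V) /
                           (1 + exp(-0.1 * (V + 32))))
        else c((-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
                 (V + 37.78) / (1 + exp(0.311 * (V + 79.23))),
               0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))),
    d = c(0.095 * exp(-0.01 * (V - 5)) / (1 + exp(-0.072 * (V - 5))),
          0.07 * exp(-0.017 * (V + 44)) / (1 + exp(0.05 * (V + 44)))),
    f = c(0.012 * exp(-0.008 * (V + 28)) / (1 + exp(0.15 * (V + 28))),
          0.0065 * exp(-0.02 * (V + 30)) / (1 + exp(-0.2 * (V + 30)))),
    x = c(0.0005 * exp(0.083 * (V + 50)) / (1 + exp(0.057 * (V + 50))),
          0.0013 * exp(-0.06 * (V + 20)) / (1 + exp(-0.04 * (V + 20)))),
    stop("oracle: unknown gate"))
  if (gate %in% c("xtof", "ytof")) stop("use oracle_ito_rates")
  scl <- switch(gate, d = kd, f = kf, 1)
  list(y_inf = ab[1] / sum(ab), tau_y = scl / sum(ab))
}

oracle_ito_rates <- function(gate, V) {
  if (gate == "xtof")
    list(y_inf = 1 / (1 + exp(-(V + 3) / 15)),
         tau_y = 3.5 * exp(-(V / 30)^2) + 1.5)
  else
    list(y_inf = 1 / (1 + exp((V + 33.5) / 10)),
         tau_y = 20 / (1 + exp((V + 33.5) / 10)) + 20)
}

oracle_currents <- function(s, p) {
  V <- s[["V"]]
  esi <- 7.7 - 13.0287 * log(s[["Cai"]])
  xi <- if (V <= -100) 1
        else if (abs(V + 77) < 1e-7) 2.837 * 0.04 / exp(0.04 * (V + 35))
        else 2.837 * (exp(0.04 * (V + 77)) - 1) / ((V + 77) * exp(0.04 * (V + 35)))
  ak1 <- 1.02 / (1 + exp(0.2385 * (V - p$EK1 - 59.215)))
  bk1 <- (0.49124 * exp(0.08032 * (V - p$EK1 + 5.476)) +
            exp(0.06175 * (V - p$EK1 - 594.31))) /
         (1 + exp(-0.5143 * (V - p$EK1 + 4.753)))
  kp <- 1 / (1 + exp((7.488 - V) / 5.98))
  list(
    INa = p$GNa * s[["m"]]^3 * s[["h"]] * s[["j"]] * (V - p$ENa),
    ISi = p$Gsi * s[["d"]] * s[["f"]] * (V - esi),
    IK = p$GK * s[["x"]] * xi * (V - p$EK),
    IK1 = p$GK1 * ak1 / (ak1 + bk1) * (V - p$EK1),
    IKp = p$GKp * kp * (V - p$EKp),
    Ib = p$Gb * (V - p$Eb),
    Itof = p$Gtof * s[["xtof"]] * s[["ytof"]] * (V - p$Etof),
    ESi = esi)
}

# brute-force pseudo-ECG evaluation, independent of the package kernel
oracle_ecg <- function(V, dx, probe) {
  ny <- nrow(V); nx <- ncol(V)
  acc <- 0
  for (j in 1:nx) for (i in 1:ny) {
    jl <- max(j - 1, 1)
    jr <- min(j + 1, nx)
    il <- max(i - 1, 1)
    ir <- min(i + 1, ny)
    dvdx <- (V[i, jr] - V[i, jl]) / (2 * dx)
    dvdy <- (V[ir, j] - V[il, j]) / (2 * dx)
    rx <- (j - 1) * dx - probe[1]
    ry <- (i - 1) * dx - probe[2]
    rz <- -probe[3]
    r3 <- (rx^2 + ry^2 + rz^2)^1.5
    acc <- acc + dvdx * (-rx / r3) + dvdy * (-ry / r3)
  }
  acc * dx^2
}

# shared expensive runs, computed once per test session
.cw_cache <- new.env(parent = emptyenv())
shared <- function(name, expr) {
  if (is.null(.cw_cache[[name]])) .cw_cache[[name]] <- force(expr)
  .cw_cache[[name]]
}

prepaced_state <- function() {
  shared("prepaced_500", prepace_cell(model_params(),
                                      pacing_protocol(pcl = 500, n_beats = 50)))
}
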