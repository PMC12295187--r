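#' Construct a full single-cell state
#'
#' The state holds the membrane potential `V` (mV), the eight
#' Hodgkin-Huxley-type gate variables (`m`, `h`, `j` for INa; `d`, `f` for the
#' slow-inward calcium current; `x` for IK; `xtof`, `ytof` for Ito,f) and the
#' intracellular calcium concentration `Cai` (mM).
#'
#' @param V membrane potential (mV).
#' @param m,h,j,d,f,x,xtof,ytof gate variables, each in \[0, 1\].  Defaults are
#'   the steady-state values at `V` so a freshly built state is consistent.
#' @param Cai intracellular calcium (mM, > 0).
#' @param params `cw_params`, used for the gate steady states.
#' @return Named numeric vector of class `cw_state`.
#' @examples
#' s <- cell_state()
#' s["V"]
#' @export
cell_state <- function(V = -84, m = NULL, h = NULL, j = NULL, d = NULL,
                       f = NULL, x = NULL, xtof = NULL, ytof = NULL,
                       Cai = 2e-4, params = model_params()) {
  if (!is.finite(V)) stop("V must be finite")
  if (!is.finite(Cai) || Cai <= 0) stop("Cai must be positive")
  kin <- cw_gate_kinetics(V, params$kd, params$kf)
  gates <- list(m = m, h = h, j = j, d = d, f = f, x = x,
                xtof = xtof, ytof = ytof)
  for (g in seq_along(gates)) {
    if (is.null(gates[[g]])) gates[[g]] <- kin[g, 1]
    if (!is.finite(gates[[g]]) || gates[[g]] < 0 || gates[[g]] > 1)
      stop("gate ", .gate_names[g], " must lie in [0, 1]")
  }
  s <- c(V, unlist(gates, use.names = FALSE), Cai)
  names(s) <- .state_names
  class(s) <- "cw_state"
  s
}

#' @export
print.cw_state <- function(x, ...) {
  cat(sprintf("Cell state: V = %.3f mV, Cai = %.3g mM\n", x[["V"]], x[["Cai"]]))
  g <- x[2:9]
  cat("  gates:", paste(sprintf("%s=%.4f", names(g), g), collapse = " "), "\n")
  invisible(x)
}

as_cw_state <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 10)
  names(v) <- .state_names
  class(v) <- "cw_state"
  v
}

#' Gate steady state and time constant at a voltage
#'
#' Evaluates the Hodgkin-Huxley steady state `y_inf(V)` and time constant
#' `tau_y(V)` for one gate.  The scale factors `kd`/`kf` in `params` multiply
#' tau_d and tau_f only; every other gate is unaffected.
#'
#' @param gate_id one of `"m"`, `"h"`, `"j"`, `"d"`, `"f"`, `"x"`, `"xtof"`,
#'   `"ytof"`.
#' @param V membrane potential (mV), finite.
#' @param params `cw_params`.
#' @return List with `y_inf` and `tau_y` (ms).
#' @examples
#' gate_kinetics("d", -40)
#' gate_kinetics("d", -40, model_params(kd = 0.3))
#' @export
gate_kinetics <- function(gate_id, V, params = model_params()) {
  if (!is.character(gate_id) || length(gate_id) != 1 ||
      !(gate_id %in% .gate_names))
    stop("unknown gate_id: ", paste(gate_id, collapse = ", "))
  if (!is.numeric(V) || length(V) != 1 || !is.finite(V))
    stop("V must be a single finite number")
  k <- cw_gate_kinetics(V, params$kd, params$kf)
  i <- match(gate_id, .gate_names)
  list(y_inf = k[i, 1], tau_y = k[i, 2])
}

#' Ionic current breakdown at a state
#'
#' Evaluates the seven membrane currents of the modified LR1 cell
#' (INa, ISi, IK, IK1, IKp, Ib, Ito,f) and their sum `Iion`, together with the
#' calcium-dependent slow-inward reversal potential `ESi`.
#'
#' @param state `cw_state`.
#' @param params `cw_params`.
#' @return List of class `cw_currents` with the seven components (uA/cm^2),
#'   `Iion`, and `ESi` (mV).
#' @examples
#' total_current(cell_state())$Iion
#' @export
total_current <- function(state, params = model_params()) {
  v <- cw_currents(as.numeric(state), params)
  structure(as.list(v), class = "cw_currents")
}

#' @export
print.cw_currents <- function(x, ...) {
  cat("Membrane currents (uA/cm^2):\n")
  for (nm in c("INa", "ISi", "IK", "IK1", "IKp", "Ib", "Itof"))
    cat(sprintf("  %-4s %10.4f\n", nm, x[[nm]]))
  cat(sprintf("  Iion %10.4f   (ESi = %.2f mV)\n", x$Iion, x$ESi))
  invisible(x)
}

#' Advance a cell by one time step
#'
#' Explicit forward-Euler update of `V` and `Cai` with a Rush-Larsen
#' exponential update of all gates, evaluated at the pre-step voltage.  The
#' voltage equation is `dV/dt = -(Iion - Istim)/Cm`, so a positive `Istim`
#' depolarizes the cell.
#'
#' @param state `cw_state`.
#' @param Istim stimulus current density (uA/cm^2, positive = depolarizing).
#' @param dt time step (ms); the default 0.01 ms is the working resolution,
#'   values above 0.02 ms are rejected.
#' @param params `cw_params`.
#' @return The advanced `cw_state`.
#' @examples
#' s <- step_cell(cell_state(), Istim = 40)
#' @export
step_cell <- function(state, Istim = 0, dt = 0.01, params = model_params()) {
  if (!is.numeric(dt) || dt <= 0 || dt > 0.02)
    stop("dt must be in (0, 0.02] ms")
  as_cw_state(cw_cell_step(as.numeric(state), Istim, dt, params))
}

#' Simulate a single cell under a train of stimulus pulses
#'
#' Integrates the cell ODE for `duration` ms with rectangular stimulus pulses
#' at the given onset times, recording the voltage trace.
#'
#' @param state initial `cw_state`.
#' @param params `cw_params`.
#' @param duration total simulated time (ms).
#' @param stim_onsets numeric vector of pulse onset times (ms), sorted.
#' @param stim_amplitude,stim_duration pulse amplitude (uA/cm^2) and width (ms).
#' @param dt time step (ms).
#' @param record_dt trace sampling interval (ms); 0 records no trace.
#' @param exact if `TRUE` evaluate the rate functions exactly at every step
#'   instead of using the voltage-indexed lookup tables.
#' @return List of class `cw_trace`: data frame `trace` (`t_ms`, `V_mV`,
#'   `Cai_mM`), `final_state`, and the call settings.
#' @examples
#' tr <- simulate_cell(duration = 400, stim_onsets = 10)
#' max(tr$trace$V_mV)
#' @export
simulate_cell <- function(state = cell_state(), params = model_params(),
                          duration = 500, stim_onsets = numeric(),
                          stim_amplitude = default_stimulus()$amplitude,
                          stim_duration = default_stimulus()$duration,
                          dt = 0.01, record_dt = 0.1, exact = FALSE) {
  r <- cw_cell_run(as.numeric(state), params, dt, duration,
                   as.numeric(stim_onsets), stim_amplitude, stim_duration,
                   record_dt, !exact)
  if (isTRUE(r$blowup))
    stop(sprintf("numerical blow-up at t = %.2f ms", r$t_blowup))
  tr <- if (record_dt > 0)
    data.frame(t_ms = r$t, V_mV = r$V, Cai_mM = r$Cai)
  else
    data.frame(t_ms = numeric(), V_mV = numeric(), Cai_mM = numeric())
  structure(list(trace = tr, final_state = as_cw_state(r$final_state),
                 params = params, dt = dt),
            class = "cw_trace")
}

#' @export
print.cw_trace <- function(x, ...) {
  cat(sprintf("Cell trace: %d samples over %.1f ms\n",
              nrow(x$trace), if (nrow(x$trace)) max(x$trace$t_ms) else 0))
  invisible(x)
}

#' Relax a cell to its resting steady state
#'
#' Integrates the unstimulated cell until the voltage drift `|dV/dt|` falls
#' below `tol` and then snaps all gates to their steady-state values at the
#' resting potential.
#'
#' @param params `cw_params`.
#' @param tol drift tolerance (mV/ms, > 0).
#' @param max_t time bound (ms) before giving up.
#' @return Resting `cw_state`.
#' @examples
#' resting_state()["V"]
#' @export
resting_state <- function(params = model_params(), tol = 1e-9, max_t = 60000) {
  if (tol <= 0) stop("tol must be positive")
  # relaxation integration without stimulus, to land in the resting basin
  s <- cell_state(params = params)
  t <- 0
  repeat {
    r <- cw_cell_run(as.numeric(s), params, 0.01, 500, numeric(), 0, 0, 0, TRUE)
    s <- as_cw_state(r$final_state)
    t <- t + 500
    dv <- abs(total_current(s, params)$Iion) / params$Cm
    if (dv < 1e-4 || t >= max_t) break
  }
  # polish to the exact fixed point: gates at y_inf(V), Cai balancing the
  # calcium equation, V a root of Iion(V)
  state_at <- function(v) {
    cai <- .cai_balance(v, params)
    cell_state(V = v, Cai = cai, params = params)
  }
  iion_at <- function(v) total_current(state_at(v), params)$Iion
  v0 <- s[["V"]]
  root <- tryCatch(
    stats::uniroot(iion_at, interval = c(v0 - 3, v0 + 3), tol = 1e-12),
    error = function(e) NULL)
  if (!is.null(root)) s <- state_at(root$root)
  dv <- abs(total_current(s, params)$Iion) / params$Cm
  if (dv >= tol)
    stop("no convergence to rest within ", max_t, " ms (|dV/dt| = ", dv, ")")
  s
}

# Cai at which the calcium balance is stationary for fixed V, gates at rest
.cai_balance <- function(v, params) {
  kin <- cw_gate_kinetics(v, params$kd, params$kf)
  df <- kin[4, 1] * kin[5, 1]
  g <- function(cai)
    -1e-4 * params$Gsi * df * (v - 7.7 + 13.0287 * log(cai)) +
      0.07 * (1e-4 - cai)
  stats::uniroot(g, interval = c(1e-7, 1e-2), tol = 1e-15)$root
}

#' Diastolic stimulus threshold by bisection
#'
#' Finds the smallest rectangular-pulse amplitude that elicits an action
#' potential (peak V above 0 mV) from a given state, by bisection on the
#' amplitude.
#'
#' @param state starting `cw_state` (default: resting state).
#' @param params `cw_params`.
#' @param duration pulse width (ms).
#' @param bracket amplitude bracket (uA/cm^2).
#' @param resolution bisection resolution (uA/cm^2).
#' @return Threshold amplitude (uA/cm^2).
#' @examples
#' \donttest{find_stim_threshold()}
#' @export
find_stim_threshold <- function(state = NULL, params = model_params(),
                                duration = 1, bracket = c(2, 200),
                                resolution = 0.5) {
  if (is.null(state)) state <- resting_state(params)
  fires <- function(a) {
    r <- cw_cell_run(as.numeric(state), params, 0.01, 50, 0, a, duration,
                     0.1, TRUE)
    max(r$V) > 0
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (fires(lo)) return(lo)
  if (!fires(hi)) stop("no capture at the upper bracket amplitude")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}
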