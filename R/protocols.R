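#' Pacing protocol
#'
#' A periodic train of identical rectangular stimulus pulses.
#'
#' @param pcl pacing cycle length (ms).
#' @param n_beats number of beats (>= 1).
#' @param pulse_amplitude stimulus amplitude (uA/cm^2).
#' @param pulse_duration pulse width (ms), shorter than `pcl`.
#' @return Object of class `cw_pacing`.
#' @examples
#' pacing_protocol(pcl = 500, n_beats = 50)
#' @export
pacing_protocol <- function(pcl = 500, n_beats = 1000,
                            pulse_amplitude = default_stimulus()$amplitude,
                            pulse_duration = default_stimulus()$duration) {
  if (!is.numeric(n_beats) || n_beats < 1 || n_beats != round(n_beats))
    stop("n_beats must be a positive integer")
  if (!(pcl > pulse_duration && pulse_duration > 0))
    stop("need pcl > pulse_duration > 0")
  structure(list(pcl = pcl, n_beats = as.integer(n_beats),
                 pulse_amplitude = pulse_amplitude,
                 pulse_duration = pulse_duration),
            class = "cw_pacing")
}

#' @export
print.cw_pacing <- function(x, ...) {
  cat(sprintf("Pacing: %d beats at PCL %g ms (%g uA/cm^2 x %g ms)\n",
              x$n_beats, x$pcl, x$pulse_amplitude, x$pulse_duration))
  invisible(x)
}

#' Pre-pace a cell to its pacing steady state
#'
#' Stimulates a single cell periodically and returns the full state recorded
#' at the end of the last cycle.  That state initializes every cell of a
#' tissue simulation, emulating the standard pre-pacing wash-out of
#' transients (the reference protocol is 1000 beats at PCL 500 ms; a reduced
#' beat count is adequate once the beat-to-beat APD change has converged and
#' is what the bundled experiments use).
#'
#' @param params `cw_params`.
#' @param protocol `cw_pacing`.
#' @param state optional starting `cw_state` (default: resting state).
#' @param dt time step (ms).
#' @return `cw_state` at the end of pacing.
#' @examples
#' s <- prepace_cell(protocol = pacing_protocol(pcl = 500, n_beats = 5))
#' @export
prepace_cell <- function(params = model_params(),
                         protocol = pacing_protocol(),
                         state = NULL, dt = 0.01) {
  stopifnot(inherits(protocol, "cw_pacing"))
  if (is.null(state)) state <- resting_state(params)
  onsets <- (seq_len(protocol$n_beats) - 1) * protocol$pcl
  total <- protocol$n_beats * protocol$pcl
  r <- cw_cell_run(as.numeric(state), params, dt, total, onsets,
                   protocol$pulse_amplitude, protocol$pulse_duration, 0, TRUE)
  if (isTRUE(r$blowup))
    stop(sprintf("numerical blow-up during pre-pacing at beat %d",
                 floor(r$t_blowup / protocol$pcl) + 1))
  as_cw_state(r$final_state)
}

#' Steady-state paced voltage trace
#'
#' Pre-paces a cell and then records `n_record` further paced beats at the
#' same cycle length.  This is the work-horse behind the AP-morphology,
#' restitution and alternans measurements.
#'
#' @inheritParams prepace_cell
#' @param n_record number of recorded beats appended after pre-pacing.
#' @param record_dt trace sampling interval (ms).
#' @return `cw_trace` whose trace covers the `n_record` recorded beats
#'   (time restarts at 0 at the first recorded stimulus).
#' @examples
#' tr <- paced_trace(protocol = pacing_protocol(pcl = 500, n_beats = 3),
#'                   n_record = 2)
#' @export
paced_trace <- function(params = model_params(),
                        protocol = pacing_protocol(),
                        n_record = 2, state = NULL, dt = 0.01,
                        record_dt = 0.1) {
  s <- prepace_cell(params, protocol, state, dt)
  onsets <- (seq_len(n_record) - 1) * protocol$pcl
  simulate_cell(s, params, duration = n_record * protocol$pcl,
                stim_onsets = onsets,
                stim_amplitude = protocol$pulse_amplitude,
                stim_duration = protocol$pulse_duration,
                dt = dt, record_dt = record_dt)
}

#' S1S2 restitution schedule
#'
#' @param s1 `cw_pacing` for the S1 conditioning train.
#' @param di_list diastolic intervals to probe (ms, positive, ascending).
#' @return Object of class `cw_s1s2`.
#' @examples
#' s1s2_schedule(di_list = c(50, 100, 200, 400))
#' @export
s1s2_schedule <- function(s1 = pacing_protocol(pcl = 500, n_beats = 20),
                          di_list = c(25, 50, 100, 150, 200, 300, 500, 1000)) {
  stopifnot(inherits(s1, "cw_pacing"))
  di_list <- as.numeric(di_list)
  if (any(!is.finite(di_list)) || any(di_list <= 0) || is.unsorted(di_list))
    stop("di_list must be positive and ascending")
  structure(list(s1 = s1, di_list = di_list), class = "cw_s1s2")
}

#' APD restitution by the S1S2 (or dynamic) protocol
#'
#' S1S2 mode: a conditioning S1 train is applied once; after the final S1
#' action potential repolarizes through -75 mV, a single S2 pulse is delivered
#' at each requested diastolic interval (each DI branches from the same saved
#' post-repolarization state, so points are independent).  The DI is measured
#' from the last S1 repolarization crossing to the S2 onset, consistent with
#' the APD threshold definition.  Dynamic mode: the cell is paced to steady
#' state at a range of cycle lengths and the (DI, APD) pair of the final beat
#' of each is reported.
#'
#' @param params `cw_params`.
#' @param schedule `cw_s1s2`.
#' @param dt time step (ms).
#' @param threshold APD threshold (mV).
#' @param method `"s1s2"` or `"dynamic"` (PCLs = DI list + S1 APD).
#' @return Data frame with `di`, `apd`, `captured` (logical: did S2 elicit an
#'   AP).  Points where S2 fails to capture are flagged, not dropped.
#' @examples
#' \donttest{
#' run_s1s2(schedule = s1s2_schedule(pacing_protocol(500, 5), c(100, 500)))
#' }
#' @export
run_s1s2 <- function(params = model_params(), schedule = s1s2_schedule(),
                     dt = 0.01, threshold = -75, method = c("s1s2", "dynamic")) {
  stopifnot(inherits(schedule, "cw_s1s2"))
  method <- match.arg(method)
  s1 <- schedule$s1
  if (method == "dynamic") return(.run_dynamic(params, schedule, dt, threshold))

  # condition with n-1 beats, then record the final S1 beat until it
  # repolarizes through the threshold
  pre <- if (s1$n_beats > 1)
    prepace_cell(params, pacing_protocol(s1$pcl, s1$n_beats - 1,
                                         s1$pulse_amplitude, s1$pulse_duration),
                 dt = dt)
  else resting_state(params)

  horizon <- max(s1$pcl, 800)
  seg <- cw_cell_run(as.numeric(pre), params, dt, horizon, 0,
                     s1$pulse_amplitude, s1$pulse_duration, dt, TRUE)
  eps <- extract_apds(seg$t, seg$V, threshold = threshold)
  full <- eps[!eps$clipped, , drop = FALSE]
  if (!nrow(full)) stop("final S1 beat did not repolarize within the horizon")
  t_repol <- full$t_down[1]

  # state at the repolarization crossing (re-run up to it)
  at_rep <- cw_cell_run(as.numeric(pre), params, dt,
                        ceiling(t_repol / dt) * dt, 0,
                        s1$pulse_amplitude, s1$pulse_duration, 0, TRUE)
  s_rep <- at_rep$final_state

  out <- data.frame(di = schedule$di_list, apd = NA_real_, captured = FALSE)
  s_cur <- s_rep
  t_cur <- 0
  for (i in seq_along(schedule$di_list)) {
    di <- schedule$di_list[i]
    if (di > t_cur) {  # advance the shared unstimulated segment
      adv <- cw_cell_run(s_cur, params, dt, di - t_cur, numeric(), 0, 0, 0, TRUE)
      s_cur <- adv$final_state
      t_cur <- di
    }
    s2 <- cw_cell_run(s_cur, params, dt, 1200, 0, s1$pulse_amplitude,
                      s1$pulse_duration, dt, TRUE)
    ep <- extract_apds(s2$t, s2$V, threshold = threshold)
    ep <- ep[!ep$clipped & ep$peak_v > -40, , drop = FALSE]
    if (nrow(ep)) {
      out$apd[i] <- ep$apd[1]
      out$captured[i] <- TRUE
    }
  }
  if (!any(out$captured))
    stop("S2 failed to elicit an action potential at every DI")
  out
}

.run_dynamic <- function(params, schedule, dt, threshold) {
  pcls <- schedule$di_list + 200  # probe cycle lengths spanning the DI range
  out <- data.frame(di = NA_real_, apd = NA_real_,
                    captured = FALSE)[0, ]
  for (pcl in pcls) {
    pr <- pacing_protocol(pcl, max(schedule$s1$n_beats, 10),
                          schedule$s1$pulse_amplitude,
                          schedule$s1$pulse_duration)
    tr <- paced_trace(params, pr, n_record = 2, dt = dt)
    eps <- extract_apds(tr$trace$t_ms, tr$trace$V_mV, threshold = threshold)
    eps <- eps[!eps$clipped, , drop = FALSE]
    if (nrow(eps) >= 2) {
      di <- eps$t_up[2] - eps$t_down[1]
      out <- rbind(out, data.frame(di = di, apd = eps$apd[2], captured = TRUE))
    }
  }
  out[order(out$di), , drop = FALSE]
}

#' Cross-field spiral-induction protocol
#'
#' A plane wave is launched from the left edge; once the center cell has
#' depolarized above the trigger level and then fallen back below it, every
#' cell in the bottom half of the sheet is clamped to `clamp_voltage` for
#' `clamp_duration` ms, which breaks the repolarization tail and curls a
#' spiral pair in the interior.
#'
#' @param trigger_level trigger voltage at the center cell (mV).
#' @param clamp_voltage clamp value (mV).
#' @param clamp_duration clamp window (ms, > 0).
#' @param stim_cols width of the left-edge pacing strip (columns).
#' @param trigger_timeout abort if the trigger has not fired by this time (ms).
#' @return Object of class `cw_crossfield`.
#' @examples
#' cross_field_protocol()
#' @export
cross_field_protocol <- function(trigger_level = -55, clamp_voltage = -30,
                                 clamp_duration = 2, stim_cols = 5,
                                 trigger_timeout = 2000) {
  if (clamp_duration <= 0) stop("clamp_duration must be positive")
  structure(list(trigger_level = trigger_level, clamp_voltage = clamp_voltage,
                 clamp_duration = clamp_duration, stim_cols = stim_cols,
                 trigger_timeout = trigger_timeout),
            class = "cw_crossfield")
}

#' @export
print.cw_crossfield <- function(x, ...) {
  cat(sprintf(paste0("Cross-field induction: left strip %d cols; trigger %g mV",
                     " at center; clamp bottom half to %g mV for %g ms\n"),
              x$stim_cols, x$trigger_level, x$clamp_voltage, x$clamp_duration))
  invisible(x)
}
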