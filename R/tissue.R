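#' Construct a 2D tissue field
#'
#' A lattice of cells sharing one parameter set, coupled by voltage diffusion
#' (monodomain model) with no-flux boundaries.  Rows index the y coordinate
#' (increasing downward), columns the x coordinate; "bottom half" means rows
#' `>= ny/2`.
#'
#' @param nx,ny grid size (columns, rows; each >= 3).
#' @param state uniform initial `cw_state` for every site.
#' @param dx lattice spacing (cm; the grid is isotropic).
#' @param D diffusion constant (cm^2/ms).
#' @param t current time (ms).
#' @return Object of class `cw_tissue`: list of ten `ny x nx` state matrices
#'   plus geometry.
#' @examples
#' f <- tissue_field(8, 8, cell_state())
#' dim(f$V)
#' @export
tissue_field <- function(nx, ny, state = cell_state(), dx = 0.0125,
                         D = 0.001, t = 0) {
  if (nx < 3 || ny < 3) stop("nx and ny must be at least 3")
  if (D < 0) stop("D must be non-negative")
  f <- lapply(seq_along(.state_names), function(q)
    matrix(as.numeric(state)[q], ny, nx))
  names(f) <- .state_names
  f$nx <- as.integer(nx); f$ny <- as.integer(ny)
  f$dx <- dx; f$D <- D; f$t <- t
  class(f) <- "cw_tissue"
  f
}

#' @export
print.cw_tissue <- function(x, ...) {
  cat(sprintf("Tissue %d x %d (dx = %g cm, D = %g cm^2/ms, t = %g ms)\n",
              x$nx, x$ny, x$dx, x$D, x$t))
  invisible(x)
}

#' Advance a tissue field by one explicit step
#'
#' Five-point Laplacian with zero-flux ghost nodes (boundary-value copy) plus the per-site
#' ionic update; the stability bound `dt < dx^2 / (4 D)` is enforced at call
#' time.  `diffusion_only = TRUE` freezes the ionic model (`Iion = 0`), which
#' is useful for verifying discrete conservation and the heat-kernel limit.
#'
#' @param field `cw_tissue`.
#' @param dt time step (ms).
#' @param params `cw_params`.
#' @param stimulus optional `ny x nx` matrix of stimulus current densities
#'   (uA/cm^2, positive depolarizes).
#' @param diffusion_only logical.
#' @return The advanced `cw_tissue`.
#' @examples
#' f <- tissue_field(8, 8)
#' f2 <- step_tissue(f)
#' @export
step_tissue <- function(field, dt = 0.01, params = model_params(),
                        stimulus = NULL, diffusion_only = FALSE) {
  stopifnot(inherits(field, "cw_tissue"))
  if (!is.null(stimulus) &&
      !all(dim(stimulus) == c(field$ny, field$nx)))
    stop("stimulus matrix shape must match the grid")
  out <- cw_tissue_step(field[.state_names], params, dt, field$D, field$dx,
                        stimulus, diffusion_only)
  for (nm in .state_names) field[[nm]] <- out[[nm]]
  field$t <- field$t + dt
  field
}

#' Conduction velocity on a 1D cable
#'
#' Launches a single wavefront by stimulating the first sites of a cable
#' initialized uniformly from a (pre-paced) state, and measures the speed
#' between two interior sensors in the middle half of the cable from their
#' linearly interpolated upstroke times (crossing of `upstroke_v`).
#'
#' @param params `cw_params`.
#' @param n cable length in sites.
#' @param dx spacing (cm).
#' @param D diffusion constant (cm^2/ms).
#' @param state initial state for every site (default: pre-paced, 50 beats at
#'   PCL 500 ms).
#' @param dt time step (ms).
#' @param stim_sites,stim_amplitude,stim_duration stimulus applied to the
#'   first `stim_sites` sites.
#' @param sensors two 1-based site indices (defaults sit in the middle half).
#' @param upstroke_v upstroke detection threshold (mV).
#' @param t_max simulation horizon (ms).
#' @return List of class `cw_cv`: `cv_m_s`, sensor times, settings.
#' @examples
#' \donttest{measure_cv()$cv_m_s}
#' @export
measure_cv <- function(params = model_params(), n = 400, dx = 0.0125,
                       D = 0.001, state = NULL, dt = 0.01,
                       stim_sites = 5,
                       stim_amplitude = 2 * default_stimulus()$amplitude,
                       stim_duration = default_stimulus()$duration,
                       sensors = c(150, 250), upstroke_v = -40,
                       t_max = 120) {
  if (any(sensors < n / 4) || any(sensors > 3 * n / 4))
    stop("sensors must sit in the middle half of the cable")
  if (is.null(state))
    state <- prepace_cell(params, pacing_protocol(pcl = 500, n_beats = 50))
  r <- cw_cable_run(as.numeric(state), n, dx, D, params, dt, t_max,
                    stim_sites, stim_amplitude, stim_duration,
                    as.integer(sensors), dt * 5)
  if (isTRUE(r$blowup)) stop("numerical blow-up during the cable run")
  tt <- r$t
  up <- function(v) {
    i <- which(v[-1] > upstroke_v & v[-length(v)] <= upstroke_v)
    if (!length(i)) return(NA_real_)
    i <- i[1]
    tt[i] + (upstroke_v - v[i]) / (v[i + 1] - v[i]) * (tt[i + 1] - tt[i])
  }
  t1 <- up(r$traces[, 1]); t2 <- up(r$traces[, 2])
  if (is.na(t2) || is.na(t1))
    stop("propagation failure: wavefront never reached the sensors")
  dist_cm <- abs(diff(sensors)) * dx
  cv <- dist_cm / (t2 - t1) * 10  # cm/ms -> m/s
  structure(list(cv_m_s = cv, t_upstroke = c(t1, t2), sensors = sensors,
                 dx = dx, D = D, n = n),
            class = "cw_cv")
}

#' @export
print.cw_cv <- function(x, ...) {
  cat(sprintf("Conduction velocity: %.3f m/s (%d-site cable, D = %g)\n",
              x$cv_m_s, x$n, x$D))
  invisible(x)
}

#' Run a 2D spiral-wave experiment
#'
#' Initializes every site from a pre-paced state, launches a plane wave from
#' the left edge, applies the cross-field clamp (see
#' [cross_field_protocol]), and then evolves freely while recording the tip
#' track, pseudo-ECGs, site voltage traces and optional voltage snapshots.
#'
#' @param params `cw_params`.
#' @param nx,ny grid size.
#' @param dx lattice spacing (cm).
#' @param D diffusion constant (cm^2/ms).
#' @param state pre-paced `cw_state` applied uniformly (default: pre-pace at
#'   `prepace_pcl` for `prepace_beats` beats).
#' @param protocol `cw_crossfield`.
#' @param horizon total simulated time (ms).
#' @param dt time step (ms).
#' @param stim_amplitude,stim_duration plane-wave stimulus.
#' @param prepace_pcl,prepace_beats pre-pacing settings used when `state` is
#'   `NULL`.
#' @param frame_dt tip/analysis frame interval (ms).
#' @param lag_ms phase-embedding lag (ms).
#' @param v_star phase-embedding origin (mV).
#' @param probes pseudo-ECG probe matrix (`k x 3`, cm); default
#'   [default_probes] geometry.
#' @param ecg_dt pseudo-ECG sampling interval (ms; 0 disables).
#' @param trace_sites 1-based linear site indices whose voltage is recorded
#'   (default: a 3x3 grid of interior sites).
#' @param trace_dt site-trace sampling interval (ms).
#' @param snapshot_times times (ms) at which full voltage fields are kept.
#' @return Object of class `cw_run` with elements `events`, `tips`
#'   (`t`, `count`, `xy`), `ecg` (data frame), `traces`, `snapshots`,
#'   `V_final`, and the run geometry.
#' @examples
#' \donttest{
#' run <- run_spiral(model_params(Gsi = 0.01, kd = 0.3, kf = 0.3),
#'                   nx = 96, ny = 96, horizon = 300)
#' }
#' @export
run_spiral <- function(params = model_params(), nx = 384, ny = 384,
                       dx = 0.0125, D = 0.001, state = NULL,
                       protocol = cross_field_protocol(), horizon = 4000,
                       dt = 0.01,
                       stim_amplitude = 2 * default_stimulus()$amplitude,
                       stim_duration = default_stimulus()$duration,
                       prepace_pcl = 2000, prepace_beats = 50,
                       frame_dt = 5, lag_ms = 2, v_star = -30,
                       probes = NULL, ecg_dt = 1,
                       trace_sites = NULL, trace_dt = 0.5,
                       snapshot_times = numeric()) {
  stopifnot(inherits(protocol, "cw_crossfield"))
  if (is.null(state))
    state <- prepace_cell(params, pacing_protocol(pcl = prepace_pcl,
                                                  n_beats = prepace_beats,
                                                  pulse_amplitude = stim_amplitude,
                                                  pulse_duration = stim_duration))
  if (is.null(probes)) probes <- default_probes(nx, ny, dx)
  pm <- as.matrix(probes[, c("x", "y", "z")])
  if (is.null(trace_sites)) {
    ii <- round(ny * c(0.25, 0.5, 0.75)); jj <- round(nx * c(0.25, 0.5, 0.75))
    trace_sites <- as.integer(outer(ii, (jj - 1) * ny, "+"))
  }
  r <- cw_tissue_run(as.numeric(state), nx, ny, dx, D, params, dt, horizon,
                     protocol$stim_cols, stim_amplitude, stim_duration,
                     TRUE, protocol$trigger_level, protocol$clamp_voltage,
                     protocol$clamp_duration, protocol$trigger_timeout,
                     frame_dt, lag_ms, v_star, pm, ecg_dt,
                     as.integer(trace_sites), trace_dt,
                     as.numeric(snapshot_times), 512L)
  if (!is.null(r$error)) stop(r$error)
  if (isTRUE(r$blowup))
    warning(sprintf("numerical blow-up at t = %.1f ms; partial run returned",
                    r$t_blowup))
  ecg <- data.frame(t_ms = r$ecg_t)
  if (ncol(r$ecg) == 5 && identical(probes$name, default_probes(2, 2)$name)) {
    # default layout: three unipolar leads plus the bipolar difference
    ecg$ecg1 <- r$ecg[, 1]; ecg$ecg2 <- r$ecg[, 2]; ecg$ecg3 <- r$ecg[, 3]
    ecg$ecg4 <- r$ecg[, 4] - r$ecg[, 5]
  } else if (ncol(r$ecg)) {
    ecg <- cbind(ecg, as.data.frame(r$ecg))
  }
  structure(list(
    events = r$events,
    tips = list(t = r$tip_t, count = r$tip_count, xy = r$tip_xy),
    ecg_raw = data.frame(t_ms = r$ecg_t, r$ecg),
    ecg = ecg,
    traces = list(t = r$trace_t, V = r$traces, sites = trace_sites),
    snapshots = list(t = r$snapshot_t, V = r$snapshots),
    V_final = r$V_final,
    blowup = isTRUE(r$blowup),
    params = params, nx = nx, ny = ny, dx = dx, D = D,
    horizon = horizon, probes = probes),
    class = "cw_run")
}

#' @export
print.cw_run <- function(x, ...) {
  cat(sprintf("Spiral run: %d x %d grid, horizon %g ms\n", x$nx, x$ny,
              x$horizon))
  ev <- x$events
  if (!is.na(ev$t_clamp_on))
    cat(sprintf("  cross-field clamp at %.1f-%.1f ms\n", ev$t_clamp_on,
                ev$t_clamp_off))
  if (length(x$tips$count))
    cat(sprintf("  tips: final %d, max %d\n",
                x$tips$count[length(x$tips$count)], max(x$tips$count)))
  invisible(x)
}

#' Summarize a spiral run into a wave report
#'
#' Collects the dynamics label, tip statistics, per-site APD statistics and
#' pseudo-ECG irregularity into one serializable record.
#'
#' @param run `cw_run`.
#' @param transient transient cut (ms) passed to [classify_dynamics],
#'   measured from the end of the cross-field clamp when available.
#' @param horizon classification horizon (ms; default: run horizon).
#' @return Object of class `cw_wave_report` (plain list, JSON-friendly).
#' @examples
#' \donttest{wave_report(run)}
#' @export
wave_report <- function(run, transient = 500, horizon = NULL) {
  stopifnot(inherits(run, "cw_run"))
  if (is.null(horizon)) horizon <- max(run$tips$t)
  t0 <- run$events$t_clamp_off
  cut <- if (!is.na(t0)) t0 + transient else transient
  dyn <- classify_dynamics(run$tips, horizon = horizon, transient = cut,
                           dx = run$dx)
  apds <- tissue_apds(run)
  ecg_irr <- if (nrow(run$ecg) > 32 && ncol(run$ecg) > 1)
    apply(run$ecg[run$ecg$t_ms > cut, -1, drop = FALSE], 2, sample_entropy)
  else NULL
  structure(list(
    label = dyn$label, evidence = dyn$evidence,
    mean_apd = if (length(apds)) mean(apds) else NA_real_,
    n_apds = length(apds),
    ecg_irregularity = ecg_irr,
    events = run$events,
    params = unclass(run$params),
    grid = c(nx = run$nx, ny = run$ny), dx = run$dx, D = run$D,
    horizon = run$horizon),
    class = "cw_wave_report")
}

#' @export
print.cw_wave_report <- function(x, ...) {
  cat(sprintf("Wave report: %s; mean APD %.1f ms over %d APs\n",
              x$label, x$mean_apd, x$n_apds))
  invisible(x)
}

#' APDs observed at the recorded tissue sites
#'
#' @param run `cw_run`.
#' @param threshold APD threshold (mV).
#' @param after only count APs starting after this time (ms; default: end of
#'   the cross-field clamp).
#' @return Numeric vector of APDs pooled over the recorded sites.
#' @examples
#' \donttest{mean(tissue_apds(run))}
#' @export
tissue_apds <- function(run, threshold = -75, after = NULL) {
  if (is.null(after)) {
    after <- run$events$t_clamp_off
    if (is.na(after)) after <- 0
  }
  tt <- run$traces$t
  out <- numeric()
  for (q in seq_len(ncol(run$traces$V))) {
    eps <- extract_apds(tt, run$traces$V[, q], threshold)
    eps <- eps[!eps$clipped & eps$t_up > after, , drop = FALSE]
    out <- c(out, eps$apd)
  }
  out
}

#' Sample entropy of a trace (irregularity score)
#'
#' Standard SampEn(m, r) on a numeric series, with `r` scaled to the series
#' standard deviation; used as the pseudo-ECG irregularity score.
#'
#' @param x numeric series.
#' @param m embedding dimension.
#' @param r tolerance as a fraction of `sd(x)`.
#' @param max_n series longer than this are decimated for tractability.
#' @return Non-negative irregularity score (0 for perfectly regular series).
#' @examples
#' sample_entropy(sin(seq(0, 20, 0.1)))
#' @export
sample_entropy <- function(x, m = 2, r = 0.2, max_n = 1500) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) > max_n) x <- x[seq(1, length(x), length.out = max_n)]
  n <- length(x)
  if (n < m + 2) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  tol <- r * s
  count <- function(mm) {
    # number of template pairs within tol in Chebyshev distance
    emb <- sapply(0:(mm - 1), function(k) x[(1 + k):(n - mm + k)])
    d <- as.matrix(dist(emb, method = "maximum"))
    (sum(d <= tol) - nrow(d)) / 2
  }
  B <- count(m); A <- count(m + 1)
  if (B == 0 || A == 0) return(log(2 * (n - m)))  # saturated irregularity
  -log(A / B)
}
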