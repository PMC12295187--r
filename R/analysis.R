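#' Extract action potentials from a voltage trace
#'
#' Segments a uniformly sampled trace into suprathreshold episodes.  Crossing
#' times are linearly interpolated, so the APD does not snap to the sampling
#' grid.  Episodes truncated by either end of the trace are flagged `clipped`
#' and should be excluded from statistics.
#'
#' @param t,v time (ms) and voltage (mV) samples; a 2-column object may be
#'   passed as `t` with `v` missing.
#' @param threshold APD threshold (mV); an AP lasts while `V > threshold`.
#' @return Data frame with one row per episode: `t_up`, `t_down`, `apd`,
#'   `peak_v`, `t_peak`, `clipped`.
#' @examples
#' t <- seq(0, 300, 0.1)
#' v <- ifelse(t > 10 & t < 110, 0, -85)
#' extract_apds(t, v)$apd
#' @export
extract_apds <- function(t, v, threshold = -75) {
  if (missing(v)) {
    m <- as.matrix(t)
    t <- m[, 1]; v <- m[, 2]
  }
  if (!length(t)) stop("empty trace")
  if (length(t) != length(v)) stop("t and v lengths differ")
  above <- v > threshold
  if (!any(above))
    return(data.frame(t_up = numeric(), t_down = numeric(), apd = numeric(),
                      peak_v = numeric(), t_peak = numeric(),
                      clipped = logical()))
  d <- diff(above)
  ups <- which(d == 1)       # last index below before an up-crossing
  downs <- which(d == -1)    # last index above before a down-crossing
  cross_up <- t[ups] + (threshold - v[ups]) / (v[ups + 1] - v[ups]) *
    (t[ups + 1] - t[ups])
  cross_down <- t[downs] + (threshold - v[downs]) / (v[downs + 1] - v[downs]) *
    (t[downs + 1] - t[downs])

  starts <- c(if (above[1]) t[1], cross_up)
  start_clip <- c(if (above[1]) TRUE, rep(FALSE, length(cross_up)))
  ends <- cross_down
  end_clip <- rep(FALSE, length(ends))
  if (length(starts) > length(ends)) {
    ends <- c(ends, t[length(t)])
    end_clip <- c(end_clip, TRUE)
  }
  n <- length(starts)
  peak_v <- t_peak <- numeric(n)
  for (i in seq_len(n)) {
    sel <- t >= starts[i] & t <= ends[i]
    k <- which.max(v[sel])
    peak_v[i] <- v[sel][k]
    t_peak[i] <- t[sel][k]
  }
  data.frame(t_up = starts, t_down = ends, apd = ends - starts,
             peak_v = peak_v, t_peak = t_peak,
             clipped = start_clip | end_clip)
}

#' Beat-to-beat APD alternans magnitude
#'
#' Mean absolute successive APD difference over the last `k` beats, with an
#' alternans flag requiring both a sustained magnitude above `min_mag` and a
#' strictly alternating sign of the successive differences.
#'
#' @param apds numeric vector of APDs (ms) from steady pacing; at least 4.
#' @param k number of trailing beats used (default: all).
#' @param min_mag flag threshold (ms).
#' @return List with `magnitude` (ms) and `alternans` (logical).
#' @examples
#' alternans_magnitude(c(200, 150, 200, 150))
#' @export
alternans_magnitude <- function(apds, k = length(apds), min_mag = 5) {
  apds <- as.numeric(apds)
  if (length(apds) < 4) stop("need at least 4 APDs")
  k <- min(k, length(apds))
  tail_apds <- apds[(length(apds) - k + 1):length(apds)]
  dif <- diff(tail_apds)
  mag <- mean(abs(dif))
  alternating <- length(dif) >= 2 &&
    all(abs(dif) > min_mag) &&
    all(sign(dif[-1]) == -sign(dif[-length(dif)]))
  list(magnitude = mag, alternans = isTRUE(alternating))
}

#' Classify the morphology of a single action potential
#'
#' Locates the phase-1 notch (first local voltage minimum after the upstroke
#' peak, within the first half of the AP), tests for a dome (a later local
#' maximum exceeding the notch by at least `dome_prominence`), and flags early
#' repolarization (no dome and an APD collapsed below `er_frac` of a
#' reference APD, typically the Ito-free APD at the same cycle length).
#'
#' @param t,v one action potential (as segmented by [extract_apds]).
#' @param threshold APD threshold (mV).
#' @param dome_prominence minimum dome height above the notch (mV).
#' @param ref_apd reference APD (ms) for the early-repolarization test;
#'   `NA` disables that flag.
#' @param er_frac early-repolarization APD fraction.
#' @return List of class `cw_ap_metrics`: `apd`, `peak_v`, `notch_v`,
#'   `notch_t`, `dome_present`, `dome_v`, `early_repolarization`.
#' @examples
#' tr <- paced_trace(protocol = pacing_protocol(500, 3), n_record = 1)
#' m <- classify_morphology(tr$trace$t_ms, tr$trace$V_mV)
#' m$notch_v
#' @export
classify_morphology <- function(t, v, threshold = -75, dome_prominence = 5,
                                ref_apd = NA, er_frac = 0.5) {
  eps <- extract_apds(t, v, threshold)
  eps <- eps[!eps$clipped, , drop = FALSE]
  if (!nrow(eps)) eps <- extract_apds(t, v, threshold)
  if (!nrow(eps)) stop("no action potential in trace")
  ep <- eps[1, ]
  if (ep$peak_v < -40) stop("no upstroke (peak below -40 mV)")
  sel <- t >= ep$t_up & t <= ep$t_down
  tt <- t[sel]; vv <- v[sel]
  ipk <- which.max(vv)
  half <- ep$t_up + 0.5 * ep$apd

  # local minima strictly after the peak, inside the first half of the APD
  notch_v <- NA_real_; notch_t <- NA_real_
  dome_present <- FALSE; dome_v <- NA_real_
  n <- length(vv)
  if (ipk < n - 1) {
    dv <- diff(vv)
    mins <- which(dv[-1] > 0 & dv[-length(dv)] <= 0) + 1
    mins <- mins[mins > ipk & tt[mins] <= half]
    if (length(mins)) {
      im <- mins[1]
      notch_v <- vv[im]; notch_t <- tt[im]
      later_max <- if (im < n) max(vv[im:n]) else -Inf
      if (later_max >= notch_v + dome_prominence) {
        dome_present <- TRUE
        dome_v <- later_max
      }
    }
  }
  early <- !dome_present && !is.na(ref_apd) && ep$apd < er_frac * ref_apd
  structure(list(apd = ep$apd, peak_v = ep$peak_v,
                 notch_v = notch_v, notch_t = notch_t,
                 dome_present = dome_present, dome_v = dome_v,
                 early_repolarization = early),
            class = "cw_ap_metrics")
}

#' @export
print.cw_ap_metrics <- function(x, ...) {
  cat(sprintf("AP: APD %.1f ms, peak %.1f mV", x$apd, x$peak_v))
  if (!is.na(x$notch_v))
    cat(sprintf(", notch %.1f mV at %.1f ms", x$notch_v, x$notch_t))
  cat(sprintf(", dome %s", if (x$dome_present) sprintf("%.1f mV", x$dome_v)
              else "absent"))
  if (x$early_repolarization) cat(" [early repolarization]")
  cat("\n")
  invisible(x)
}

#' Detect phase singularities in a voltage field pair
#'
#' Time-delay embedding: the local phase is
#' `atan2(V_lagged - V*, V_now - V*)`; a spiral tip sits on any elementary
#' plaquette around which the wrapped phase differences wind by +-2*pi.
#'
#' @param V_now,V_lagged same-shape voltage matrices separated by the
#'   embedding lag (2 ms by default elsewhere in the package).
#' @param v_star embedding origin (mV).
#' @return Data frame with `x`, `y` (0-based grid units, plaquette centers)
#'   and `chirality` (+1 / -1).
#' @examples
#' v <- matrix(-80, 8, 8)
#' nrow(detect_phase_singularities(v, v))  # no wave, no tips
#' @export
detect_phase_singularities <- function(V_now, V_lagged, v_star = -30) {
  if (!all(dim(V_now) == dim(V_lagged))) stop("field shapes differ")
  m <- cw_detect_tips(V_now, V_lagged, v_star)
  data.frame(x = m[, 1], y = m[, 2], chirality = m[, 3])
}

#' Classify spiral-wave dynamics from a tip track
#'
#' Deterministic rule on the post-transient tip-count series:
#' `no_wave` if the final frame holds no phase singularity; `breakup` if at
#' least `breakup_n` tips are sustained continuously for `breakup_sustain`
#' ms; `stable` if the count stays at one (in at least 90% of frames, never
#' satisfying the breakup rule) and the core stays within `meander_bound` cm;
#' `quasiperiodic` otherwise.
#'
#' @param track list with `t` (ms), `count` (tips per frame) and optionally
#'   `xy` (list of per-frame tip coordinate matrices, grid units), as
#'   produced by [run_spiral].
#' @param horizon classification horizon (ms); the track must cover it.
#' @param transient initial transient to discard (ms, measured from the start
#'   of the track).
#' @param breakup_n,breakup_sustain breakup rule constants.
#' @param meander_bound core bounding-box diagonal separating stable from
#'   quasiperiodic (cm).
#' @param dx lattice spacing (cm), used to convert tip coordinates.
#' @return Object of class `cw_dynamics`: `label` plus evidence.
#' @examples
#' tr <- list(t = seq(0, 3000, 10), count = rep(1L, 301))
#' classify_dynamics(tr, horizon = 2500)$label
#' @export
classify_dynamics <- function(track, horizon, transient = 500,
                              breakup_n = 4, breakup_sustain = 500,
                              meander_bound = 0.5, dx = 0.0125) {
  t <- track$t; count <- track$count
  if (!length(t)) stop("empty tip track")
  if (max(t) < horizon) stop("horizon longer than the track")
  sel <- t > transient & t <= horizon
  ts <- t[sel]; cs <- count[sel]
  if (!length(ts)) stop("no frames after the transient cut")

  evidence <- list(max_count = max(cs), final_count = cs[length(cs)],
                   mean_count = mean(cs))

  # longest contiguous run with count >= breakup_n
  run_ms <- 0
  if (any(cs >= breakup_n)) {
    r <- rle(cs >= breakup_n)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hits <- which(r$values)
    run_ms <- max(ts[ends[hits]] - ts[starts[hits]])
  }
  evidence$breakup_run_ms <- run_ms

  label <- if (cs[length(cs)] == 0 && run_ms < breakup_sustain) {
    "no_wave"
  } else if (run_ms >= breakup_sustain) {
    "breakup"
  } else if (mean(cs == 1) >= 0.9) {
    drift <- NA_real_
    if (!is.null(track$xy)) {
      xy <- do.call(rbind, track$xy[sel & count > 0])
      if (!is.null(xy) && nrow(xy) > 1) {
        drift <- sqrt(diff(range(xy[, 1]))^2 + diff(range(xy[, 2]))^2) * dx
      }
    }
    evidence$core_drift_cm <- drift
    if (!is.na(drift) && drift <= meander_bound) "stable" else "quasiperiodic"
  } else {
    "quasiperiodic"
  }
  structure(list(label = label, evidence = evidence), class = "cw_dynamics")
}

#' @export
print.cw_dynamics <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf("Spiral dynamics: %s (max %d tips, final %d, breakup run %.0f ms)\n",
              x$label, ev$max_count, ev$final_count, ev$breakup_run_ms))
  invisible(x)
}

#' Net topological charge of a tip set
#'
#' @param tips data frame from [detect_phase_singularities].
#' @return Sum of chiralities (integer winding number of the field boundary).
#' @examples
#' topological_charge(data.frame(x = 1, y = 1, chirality = 1))
#' @export
topological_charge <- function(tips) {
  if (!nrow(tips)) return(0)
  sum(tips$chirality)
}

#' Finite-difference restitution slope
#'
#' Slope of the APD restitution curve on the sorted (DI, APD) points.
#'
#' @param restitution data frame with `di` and `apd` (from [run_s1s2]).
#' @return Data frame with `di` (midpoints) and `slope`.
#' @examples
#' restitution_slope(data.frame(di = c(50, 100, 200), apd = c(100, 150, 180)))
#' @export
restitution_slope <- function(restitution) {
  r <- restitution[!is.na(restitution$apd), ]
  r <- r[order(r$di), ]
  if (nrow(r) < 2) stop("need at least 2 restitution points")
  data.frame(di = (r$di[-1] + r$di[-nrow(r)]) / 2,
             slope = diff(r$apd) / diff(r$di))
}
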