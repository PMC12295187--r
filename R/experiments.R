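#' Parameter sweep for spiral-wave phase diagrams
#'
#' Runs the full pre-pace / induce / evolve / classify pipeline at every
#' point of a parameter grid (e.g. `Gsi x Gtof`, or `Gsi` against a joint
#' `kd = kf` tau-scale axis named `tau_scale`), producing one dynamics label
#' per point.  Points are independent; a failed point is labelled `"failed"`
#' and the sweep continues.  Results can be appended incrementally to a CSV
#' so an interrupted sweep is restartable.
#'
#' @param axes named list of parameter value vectors; names must be
#'   `cw_params` fields or `tau_scale` (sets `kd` and `kf` jointly).
#' @param params base `cw_params` for the fixed values.
#' @param nx,ny,horizon grid size and simulated horizon (ms) per point.
#' @param prepace_pcl,prepace_beats pre-pacing per point.
#' @param transient transient cut (ms after clamp release) for
#'   classification.
#' @param out optional CSV path for incremental (crash-safe) results; rows
#'   already present are not recomputed.
#' @param ... further arguments passed to [run_spiral].
#' @return Data frame of class `cw_phase_diagram`: one row per point with the
#'   axis values, `label` and evidence columns.
#' @examples
#' \donttest{
#' run_sweep(list(Gsi = c(0.01, 0.03), tau_scale = 0.3), nx = 192, ny = 192,
#'           horizon = 1500)
#' }
#' @export
run_sweep <- function(axes, params = model_params(), nx = 384, ny = 384,
                      horizon = 4000, prepace_pcl = 2000, prepace_beats = 50,
                      transient = 500, out = NULL, ...) {
  if (!length(axes) || is.null(names(axes)) || any(names(axes) == ""))
    stop("axes must be a named list")
  ok <- names(axes) %in% c(names(unclass(model_params())), "tau_scale")
  if (!all(ok))
    stop("unknown axis name(s): ", paste(names(axes)[!ok], collapse = ", "))
  if (any(!lengths(axes))) stop("axis value lists must be non-empty")
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)

  done <- NULL
  if (!is.null(out) && file.exists(out)) done <- read.csv(out)

  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pt <- grid[i, , drop = FALSE]
    if (!is.null(done) && nrow(done)) {
      hit <- rep(TRUE, nrow(done))
      for (nm in names(pt)) hit <- hit & abs(done[[nm]] - pt[[nm]]) < 1e-12
      if (any(hit)) { rows[[i]] <- done[which(hit)[1], ]; next }
    }
    ov <- as.list(pt)
    if (!is.null(ov$tau_scale)) {
      ov$kd <- ov$tau_scale; ov$kf <- ov$tau_scale; ov$tau_scale <- NULL
    }
    pp <- do.call(update_params, c(list(params), ov))
    res <- tryCatch({
      run <- run_spiral(pp, nx = nx, ny = ny, horizon = horizon,
                        prepace_pcl = prepace_pcl,
                        prepace_beats = prepace_beats, ...)
      rep <- wave_report(run, transient = transient)
      data.frame(pt, label = rep$label,
                 max_tips = rep$evidence$max_count,
                 final_tips = rep$evidence$final_count,
                 breakup_run_ms = rep$evidence$breakup_run_ms,
                 mean_apd = rep$mean_apd)
    }, error = function(e) {
      data.frame(pt, label = "failed", max_tips = NA_integer_,
                 final_tips = NA_integer_, breakup_run_ms = NA_real_,
                 mean_apd = NA_real_)
    })
    rows[[i]] <- res
    if (!is.null(out)) {
      first <- !file.exists(out)
      suppressWarnings(write.table(res, out, sep = ",", append = !first,
                                   col.names = first, row.names = FALSE))
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("cw_phase_diagram", "data.frame")
  res
}

#' Locate a critical parameter value by bisection
#'
#' Bisects a logical predicate of one scalar parameter over a bracket where
#' the predicate changes value, to the requested resolution.  Returns the
#' final bracketing pair, not just the midpoint.
#'
#' @param predicate function of one numeric value returning `TRUE`/`FALSE`.
#' @param bracket length-2 numeric bracket.
#' @param resolution bracket width at which to stop.
#' @return List with `critical` (bracket midpoint), `lower`, `upper`, and
#'   `value_lower`, `value_upper` (predicate values at the final bracket).
#' @examples
#' find_threshold(function(x) x > 0.3, c(0, 1), 0.01)$critical
#' @export
find_threshold <- function(predicate, bracket, resolution = 0.002) {
  lo <- bracket[1]; hi <- bracket[2]
  plo <- isTRUE(predicate(lo)); phi <- isTRUE(predicate(hi))
  if (plo == phi)
    stop("predicate does not change value across the bracket")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (isTRUE(predicate(mid)) == plo) lo <- mid else hi <- mid
  }
  list(critical = (lo + hi) / 2, lower = lo, upper = hi,
       value_lower = plo, value_upper = phi)
}

#' Single-cell dome-loss (early repolarization) predicate
#'
#' `TRUE` when, at steady pacing, the cell has lost its second-stage plateau
#' on every one of the last recorded beats: no dome by the
#' [classify_morphology] rule and an APD collapsed below half the Ito-free
#' reference APD at the same cycle length.  Used to bisect the critical Gto
#' of the all-or-none early-repolarization transition.
#'
#' @param gtof Ito,f conductance to test (mS/cm^2).
#' @param params base `cw_params` (its `Gtof` is overridden).
#' @param pcl pacing cycle length (ms).
#' @param n_prepace pre-pacing beats.
#' @param n_check beats that must all be dome-less.
#' @param ref_apd Ito-free reference APD (ms); computed once if `NULL`.
#' @return Logical.
#' @examples
#' \donttest{dome_lost(0.35)}
#' @export
dome_lost <- function(gtof, params = model_params(), pcl = 500,
                      n_prepace = 50, n_check = 2, ref_apd = NULL) {
  if (is.null(ref_apd)) ref_apd <- reference_apd(params, pcl, n_prepace)
  tr <- paced_trace(update_params(params, Gtof = gtof),
                    pacing_protocol(pcl = pcl, n_beats = n_prepace),
                    n_record = n_check)
  eps <- extract_apds(tr$trace$t_ms, tr$trace$V_mV)
  eps <- eps[!eps$clipped, , drop = FALSE]
  if (nrow(eps) < n_check) return(TRUE)  # beats collapsed below threshold
  for (i in seq_len(n_check)) {
    sel <- tr$trace$t_ms >= eps$t_up[i] - 5 & tr$trace$t_ms <= eps$t_down[i] + 5
    m <- classify_morphology(tr$trace$t_ms[sel], tr$trace$V_mV[sel],
                             ref_apd = ref_apd)
    if (!m$early_repolarization) return(FALSE)
  }
  TRUE
}

#' Ito-free reference APD at a cycle length
#'
#' @param params base `cw_params` (`Gtof` forced to 0).
#' @param pcl pacing cycle length (ms).
#' @param n_prepace pre-pacing beats.
#' @return APD (ms) of a steady paced beat.
#' @examples
#' \donttest{reference_apd()}
#' @export
reference_apd <- function(params = model_params(), pcl = 500,
                          n_prepace = 50) {
  tr <- paced_trace(update_params(params, Gtof = 0),
                    pacing_protocol(pcl = pcl, n_beats = n_prepace),
                    n_record = 1)
  eps <- extract_apds(tr$trace$t_ms, tr$trace$V_mV)
  eps <- eps[!eps$clipped, , drop = FALSE]
  if (!nrow(eps)) stop("reference pacing produced no action potential")
  eps$apd[1]
}

#' Critical Gto of the early-repolarization transition
#'
#' Bisects [dome_lost] over a Gto bracket at control kinetics and steady
#' pacing.
#'
#' @param params base `cw_params`.
#' @param bracket Gto bracket (mS/cm^2).
#' @param resolution bisection resolution (mS/cm^2).
#' @param pcl,n_prepace pacing settings.
#' @return As [find_threshold].
#' @examples
#' \donttest{critical_gtof()$critical}
#' @export
critical_gtof <- function(params = model_params(), bracket = c(0.20, 0.35),
                          resolution = 0.002, pcl = 500, n_prepace = 50) {
  ref <- reference_apd(params, pcl, n_prepace)
  find_threshold(function(g) dome_lost(g, params, pcl, n_prepace,
                                       ref_apd = ref),
                 bracket, resolution)
}
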