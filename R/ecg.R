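#' Pseudo-ECG probe geometry
#'
#' The standard four-probe arrangement used for the tissue runs: ECG1 is a
#' unipolar probe 0.5 cm beyond the right edge (in-plane, mid-height), ECG2 a
#' unipolar probe 0.5 cm beyond the top edge, ECG3 a unipolar probe 1.0 cm
#' above the sheet center, and ECG4 a bipolar pair 1.0 cm above the center
#' separated by 0.1 cm.  Distances are conventions, so pseudo-ECG amplitudes
#' are in arbitrary units; only trace shape and regularity are meaningful.
#'
#' @param nx,ny grid size.
#' @param dx lattice spacing (cm).
#' @return Data frame with columns `name`, `x`, `y`, `z` (cm) and `role`
#'   (`unipolar`, `bipolar_pos`, `bipolar_neg`).
#' @examples
#' default_probes(384, 384)
#' @export
default_probes <- function(nx, ny, dx = 0.0125) {
  Lx <- (nx - 1) * dx; Ly <- (ny - 1) * dx
  data.frame(
    name = c("ecg1_right", "ecg2_top", "ecg3_above", "ecg4_pos", "ecg4_neg"),
    x = c(Lx + 0.5, Lx / 2, Lx / 2, Lx / 2 - 0.05, Lx / 2 + 0.05),
    y = c(Ly / 2, -0.5, Ly / 2, Ly / 2, Ly / 2),
    z = c(0, 0, 1.0, 1.0, 1.0),
    role = c("unipolar", "unipolar", "unipolar", "bipolar_pos", "bipolar_neg"),
    stringsAsFactors = FALSE)
}

#' Sample the extracellular potential at a probe
#'
#' Infinite-homogeneous-medium pseudo-ECG:
#' `phi = K * sum_sites grad(V) . grad(1 / |r_site - r_probe|) * dA`
#' with `K = 1` (arbitrary units).  Voltage gradients use central differences
#' with zero-flux ghost nodes (boundary-value copy), consistent with the solver.  A bipolar
#' sample is the difference of two unipolar samples.
#'
#' @param V voltage field (`ny x nx` matrix) or a `cw_tissue`.
#' @param probe numeric `c(x, y, z)` position (cm), or a row pair
#'   `list(pos, neg)` for a bipolar probe.
#' @param dx lattice spacing (cm; taken from a `cw_tissue` automatically).
#' @return Potential value (arbitrary units).
#' @examples
#' ecg_sample(matrix(-80, 16, 16), c(0.1, 0.1, 1))  # uniform field -> 0
#' @export
ecg_sample <- function(V, probe, dx = 0.0125) {
  if (inherits(V, "cw_tissue")) { dx <- V$dx; V <- V$V }
  if (is.list(probe) && length(probe) == 2)
    return(cw_ecg_sample(V, dx, as.numeric(probe[[1]])) -
           cw_ecg_sample(V, dx, as.numeric(probe[[2]])))
  cw_ecg_sample(V, dx, as.numeric(probe))
}

#' Pseudo-ECG traces from a snapshot series
#'
#' Evaluates [ecg_sample] for each probe over a sequence of voltage fields.
#'
#' @param series list with `t` (ms) and `V` (list of `ny x nx` matrices).
#' @param probes probe data frame as from [default_probes].
#' @param dx lattice spacing (cm).
#' @return Data frame of class `cw_ecg`: `t_ms` plus one column per output
#'   lead (bipolar pairs are combined into a single lead).  The sample
#'   entropy of each lead is attached as attribute `irregularity`.
#' @examples
#' s <- list(t = c(0, 1), V = list(matrix(-80, 8, 8), matrix(-70, 8, 8)))
#' ecg_trace(s, default_probes(8, 8))
#' @export
ecg_trace <- function(series, probes, dx = 0.0125) {
  if (!length(series$t)) stop("empty snapshot series")
  uni <- probes[probes$role == "unipolar", , drop = FALSE]
  pos <- probes[probes$role == "bipolar_pos", , drop = FALSE]
  neg <- probes[probes$role == "bipolar_neg", , drop = FALSE]
  out <- data.frame(t_ms = series$t)
  for (i in seq_len(nrow(uni)))
    out[[uni$name[i]]] <- vapply(series$V, function(v)
      ecg_sample(v, c(uni$x[i], uni$y[i], uni$z[i]), dx), numeric(1))
  for (i in seq_len(nrow(pos))) {
    nm <- sub("_pos$", "", pos$name[i])
    out[[nm]] <- vapply(series$V, function(v)
      ecg_sample(v, list(c(pos$x[i], pos$y[i], pos$z[i]),
                         c(neg$x[i], neg$y[i], neg$z[i])), dx), numeric(1))
  }
  attr(out, "irregularity") <-
    vapply(out[-1], sample_entropy, numeric(1))
  class(out) <- c("cw_ecg", "data.frame")
  out
}

#' Combine the raw unipolar leads of a spiral run into the four ECG leads
#'
#' @param run `cw_run` produced with the [default_probes] geometry.
#' @return Data frame `t_ms`, `ecg1` ... `ecg4` with attribute
#'   `irregularity` (per-lead sample entropy).
#' @examples
#' \donttest{run_ecg_leads(run)}
#' @export
run_ecg_leads <- function(run) {
  raw <- run$ecg_raw
  if (ncol(raw) < 6) stop("run was not recorded with the default probe set")
  out <- data.frame(t_ms = raw$t_ms,
                    ecg1 = raw[[2]], ecg2 = raw[[3]], ecg3 = raw[[4]],
                    ecg4 = raw[[5]] - raw[[6]])
  attr(out, "irregularity") <- vapply(out[-1], sample_entropy, numeric(1))
  out
}

#' Dominant spectral power fraction of a trace
#'
#' Fraction of the (mean-removed) power spectrum carried by the dominant
#' frequency and its immediate neighbours; near 1 for a periodic trace.
#'
#' @param x numeric series (uniformly sampled).
#' @return Value in (0, 1].
#' @examples
#' dominant_power_fraction(sin(seq(0, 50, 0.05)))
#' @export
dominant_power_fraction <- function(x) {
  x <- as.numeric(x); x <- x - mean(x)
  n <- length(x)
  if (n < 16 || all(x == 0)) return(NA_real_)
  p <- Mod(fft(x))^2
  p <- p[2:floor(n / 2)]
  k <- which.max(p)
  sel <- max(1, k - 1):min(length(p), k + 1)
  sum(p[sel]) / sum(p)
}
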