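#' Model parameters for the modified LR1 cell
#'
#' Conductances are in mS/cm^2 (numerically identical to mS/uF at
#' `Cm = 1` uF/cm^2), reversal potentials in mV.  `kd` and `kf` multiply the
#' L-type calcium gate time constants tau_d and tau_f; values below 1
#' accelerate the slow-inward current kinetics (e.g. `kd = kf = 0.3` reduces
#' both time constants to 30% of control).  `Gtof = 0` removes the fast
#' transient-outward current entirely, recovering the plain LR1 cell.
#'
#' Defaults are the control values used throughout: `GNa = 16` (together with
#' `D = 0.001` cm^2/ms this gives a conduction velocity of about 0.55 m/s),
#' `Gsi = 0.09`, and the LR1 potassium/background conductances at
#' `[K]o = 5.4` mM.  The Ito,f reversal defaults to the LR1 time-dependent
#' potassium reversal (`EK = -77` mV): with that choice the cell reproduces
#' the published spike-and-dome phenomenology (dome at `Gtof = 0.24`,
#' rate-dependent APD alternans near `Gtof = 0.27`), whereas the pure
#' potassium Nernst potential (-87.9 mV) collapses the dome at markedly
#' lower Gtof (see the methods vignette).
#'
#' @param GNa fast sodium conductance (mS/cm^2).
#' @param Gsi slow-inward (L-type calcium) conductance (mS/cm^2).
#' @param Gtof fast transient-outward conductance (mS/cm^2); 0 disables Ito,f.
#' @param kd,kf multiplicative scale factors on tau_d and tau_f
#'   (dimensionless; 1 = control kinetics).
#' @param GK,GK1,GKp,Gb time-dependent K, inward-rectifier, plateau K and
#'   background conductances (mS/cm^2).
#' @param Cm membrane capacitance (uF/cm^2).
#' @param ENa,EK,EK1,EKp,Eb,Etof reversal potentials (mV).
#' @param ... ignored (guards against misspelled arguments).
#' @return An object of class `cw_params` (named list).
#' @examples
#' p <- model_params(Gtof = 0.24, kd = 0.3, kf = 0.3)
#' p$Gtof
#' @export
model_params <- function(GNa = 16, Gsi = 0.09, Gtof = 0, kd = 1, kf = 1,
                         GK = 0.282, GK1 = 0.6047, GKp = 0.0183, Gb = 0.03921,
                         Cm = 1,
                         ENa = 54.4, EK = -77,
                         EK1 = 26.71 * log(5.4 / 145),
                         EKp = 26.71 * log(5.4 / 145), Eb = -59.87,
                         Etof = -77, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown parameter(s): ", paste(names(extra), collapse = ", "))
  p <- list(GNa = GNa, Gsi = Gsi, Gtof = Gtof, kd = kd, kf = kf,
            GK = GK, GK1 = GK1, GKp = GKp, Gb = Gb, Cm = Cm,
            ENa = ENa, EK = EK, EK1 = EK1, EKp = EKp, Eb = Eb, Etof = Etof)
  cond <- c("GNa", "Gsi", "Gtof", "GK", "GK1", "GKp", "Gb")
  for (nm in cond) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(nm, " must be a finite non-negative conductance")
  }
  if (!is.finite(kd) || !is.finite(kf) || kd <= 0 || kf <= 0)
    stop("kd and kf must be positive")
  if (kd > 1 || kf > 1)
    warning("kd/kf > 1 slows the calcium gates beyond control kinetics")
  if (Cm <= 0) stop("Cm must be positive")
  structure(p, class = "cw_params")
}

#' @export
print.cw_params <- function(x, ...) {
  cat("Modified LR1 cell parameters\n")
  cat(sprintf("  GNa=%g  Gsi=%g  Gtof=%g mS/cm^2;  kd=%g  kf=%g\n",
              x$GNa, x$Gsi, x$Gtof, x$kd, x$kf))
  cat(sprintf("  GK=%g  GK1=%g  GKp=%g  Gb=%g;  Cm=%g uF/cm^2\n",
              x$GK, x$GK1, x$GKp, x$Gb, x$Cm))
  cat(sprintf("  ENa=%.1f  EK=%.1f  EK1=%.2f  Etof=%.2f mV\n",
              x$ENa, x$EK, x$EK1, x$Etof))
  invisible(x)
}

#' Update a parameter set
#'
#' @param params a `cw_params` object.
#' @param ... named parameter values to replace.
#' @return A new `cw_params` object.
#' @examples
#' p <- update_params(model_params(), Gsi = 0.03)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cw_params"))
  do.call(model_params, modifyList(unclass(params), list(...)))
}

#' Read and write parameter/configuration files
#'
#' Flat key-value YAML with the parameter names used throughout (`GNa`,
#' `Gsi`, `Gtof`, `kd`, `kf`, `Cm`, ...).  Extra keys are carried through
#' unchanged, so stimulus and solver settings can live in the same file.
#'
#' @param params a `cw_params` object.
#' @param path file path.
#' @param extra optional named list of additional configuration entries.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   list with elements `params` (`cw_params`) and `extra`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_config(model_params(Gtof = 0.17), f)
#' read_config(f)$params$Gtof
#' @export
write_config <- function(params, path, extra = list()) {
  stopifnot(inherits(params, "cw_params"))
  yaml::write_yaml(c(unclass(params), extra), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(model_params))
  known <- setdiff(known, "...")
  pk <- raw[intersect(names(raw), known)]
  list(params = do.call(model_params, pk),
       extra = raw[setdiff(names(raw), known)])
}

#' Default stimulus settings
#'
#' Rectangular current pulse used by every pacing protocol: 1 ms duration at
#' roughly twice the diastolic threshold of the control cell (threshold found
#' once by bisection; see the methods vignette).
#'
#' @return Named list with `amplitude` (uA/cm^2) and `duration` (ms).
#' @examples
#' default_stimulus()
#' @export
default_stimulus <- function() {
  list(amplitude = 60, duration = 1)
}
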