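#' Write and read AP traces as CSV
#'
#' Two-column CSV (`t_ms`, `V_mV`) with a one-line `#`-prefixed metadata
#' header recording the key parameters.
#'
#' @param trace `cw_trace` or a data frame with `t_ms` and `V_mV`.
#' @param path file path.
#' @param params optional `cw_params` recorded in the header.
#' @return `write_ap_trace` returns `path` invisibly; `read_ap_trace` a data
#'   frame with attribute `metadata`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_ap_trace(data.frame(t_ms = 0:2, V_mV = c(-84, 20, -60)), f)
#' read_ap_trace(f)
#' @export
write_ap_trace <- function(trace, path, params = NULL) {
  df <- if (inherits(trace, "cw_trace")) trace$trace else trace
  if (is.null(params) && inherits(trace, "cw_trace")) params <- trace$params
  meta <- if (!is.null(params))
    sprintf("# GNa=%g Gsi=%g Gtof=%g kd=%g kf=%g", params$GNa, params$Gsi,
            params$Gtof, params$kd, params$kf)
  else "# cardiowave AP trace"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(df[, c("t_ms", "V_mV")], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ap_trace
#' @export
read_ap_trace <- function(path) {
  meta <- readLines(path, n = 1)
  df <- read.csv(path, comment.char = "#")
  attr(df, "metadata") <- sub("^#\\s*", "", meta)
  df
}

#' Persist and restore a snapshot series
#'
#' Stores a voltage snapshot series (frames plus embedded parameters and
#' geometry) in a single serialized container.
#'
#' @param series list with `t`, `V` (list of matrices) and optional metadata.
#' @param path file path (`.rds`).
#' @return `write_snapshots` returns `path` invisibly; `read_snapshots` the
#'   series list.
#' @examples
#' f <- tempfile(fileext = ".rds")
#' write_snapshots(list(t = 0, V = list(matrix(-80, 4, 4))), f)
#' length(read_snapshots(f)$V)
#' @export
write_snapshots <- function(series, path) {
  if (is.unsorted(series$t, strictly = TRUE) && length(series$t) > 1)
    stop("snapshot times must be strictly increasing")
  saveRDS(series, path)
  invisible(path)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(path) readRDS(path)

#' Serialize a wave report to JSON
#'
#' @param report `cw_wave_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @examples
#' \donttest{write_wave_report(rep, "report.json")}
#' @export
write_wave_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
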