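#' Light-scattering forward-model parameters
#'
#' @param sds smallest detectable species, in subunits (detection floor
#'   of the photodetector; an optimization parameter when fitting).
#' @param s overall scale factor, arbitrary units per uM-subunit^2.
#' @param n largest simulated species entering the sum.
#' @return A `"scattering_params"` list.
#' @export
scattering_params <- function(sds = 30L, s = 1, n = 2000L) {
  if (sds < 1 || sds > n) stop("need 1 <= sds <= n")
  if (s <= 0) stop("scale factor s must be > 0")
  structure(list(sds = as.integer(sds), s = s, n = as.integer(n)),
            class = "scattering_params")
}

#' Forward-model a bulk light-scattering trace
#'
#' The scattering contribution of an oligomer scales with its
#' concentration and squared molecular mass (number of subunits):
#' `signal(t) = s * sum_{i=sds}^{n} i^2 [A_i](t)`, primed and unprimed
#' states summed per size. Species below the detection floor `sds`
#' contribute nothing.
#'
#' @param dist a `"distribution_timecourse"` covering species up to
#'   `params$n`.
#' @param params a [scattering_params()].
#' @return A `"scattering_trace"` list with `times`, `signal`, `params`
#'   and `provenance = "simulated"`.
#' @export
scattering_signal <- function(dist, params) {
  stopifnot(inherits(dist, "distribution_timecourse"),
            inherits(params, "scattering_params"))
  tot <- species_totals(dist)
  n <- min(params$n, ncol(tot))
  if (params$sds > n) stop("sds exceeds the largest simulated species")
  i <- params$sds:n
  signal <- params$s * as.numeric(tot[, i, drop = FALSE] %*% (i^2))
  structure(list(times = dist$times, signal = signal, params = params,
                 provenance = "simulated"),
            class = "scattering_trace")
}

#' Construct a scattering trace from raw columns
#'
#' @param times time stamps, s (uniform spacing expected).
#' @param signal scattering signal, arbitrary units.
#' @param params optional [scattering_params()] metadata.
#' @param provenance `"simulated"`, `"experimental"` or `"synthetic"`.
#' @return A `"scattering_trace"`.
#' @export
scattering_trace <- function(times, signal,
                             params = NULL,
                             provenance = c("experimental", "simulated",
                                            "synthetic")) {
  provenance <- match.arg(provenance)
  times <- as.numeric(times); signal <- as.numeric(signal)
  if (length(times) != length(signal)) stop("times/signal length mismatch")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (length(times) > 2) {
    dt <- diff(times)
    if (max(abs(dt - dt[1])) > 1e-6 * abs(dt[1])) {
      stop("times must be uniformly spaced")
    }
  }
  structure(list(times = times, signal = signal, params = params,
                 provenance = provenance),
            class = "scattering_trace")
}

#' Scale a simulated trace onto an experimental one
#'
#' Chooses the affine map `a * signal + b` so that the simulated means
#' over the first and last `window` points match the corresponding
#' experimental window means exactly (two-point affine solve). With
#' `mode = "scale"` only `a` is fitted (`b = 0`), by least squares over
#' the two windows.
#'
#' @param sim simulated `"scattering_trace"`.
#' @param exp experimental `"scattering_trace"`.
#' @param window number of edge points entering each window mean.
#' @param mode `"affine"` or `"scale"`.
#' @return The scaled trace, with attributes `a` and `b`.
#' @export
scale_to_experiment <- function(sim, exp, window = 10L,
                                mode = c("affine", "scale")) {
  stopifnot(inherits(sim, "scattering_trace"),
            inherits(exp, "scattering_trace"))
  mode <- match.arg(mode)
  window <- as.integer(window)
  if (window < 1) stop("window must be >= 1")
  if (window > length(sim$signal) || window > length(exp$signal)) {
    stop("window larger than trace length")
  }
  s_start <- mean(utils::head(sim$signal, window))
  s_end <- mean(utils::tail(sim$signal, window))
  e_start <- mean(utils::head(exp$signal, window))
  e_end <- mean(utils::tail(exp$signal, window))
  tol <- 1e-12 * max(abs(sim$signal), 1)
  if (mode == "affine") {
    if (abs(s_end - s_start) <= tol) {
      if (abs(e_end - e_start) <= tol) {
        a <- 1; b <- e_start - s_start
      } else {
        stop("flat simulated trace cannot match distinct experimental ",
             "start/end levels")
      }
    } else {
      a <- (e_end - e_start) / (s_end - s_start)
      b <- e_start - a * s_start
    }
  } else {
    denom <- s_start^2 + s_end^2
    if (denom <= tol^2) stop("all-zero simulated trace cannot be scaled")
    a <- (e_start * s_start + e_end * s_end) / denom
    b <- 0
  }
  out <- sim
  out$signal <- a * sim$signal + b
  attr(out, "a") <- a
  attr(out, "b") <- b
  out
}

#' Write / read scattering traces as columnar text
#'
#' CSV columns `time_s`, `signal_au`, with a JSON metadata sidecar
#' (`<path>.json`) carrying `sds`, `s` and provenance.
#'
#' @param trace a `"scattering_trace"`.
#' @param path CSV file path.
#' @return `path` (write) or a `"scattering_trace"` (read).
#' @export
write_scattering_trace <- function(trace, path) {
  stopifnot(inherits(trace, "scattering_trace"))
  utils::write.csv(data.frame(time_s = trace$times,
                              signal_au = trace$signal),
                   path, row.names = FALSE)
  meta <- list(provenance = trace$provenance,
               sds = if (is.null(trace$params)) NA else trace$params$sds,
               s = if (is.null(trace$params)) NA else trace$params$s)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scattering_trace
#' @export
read_scattering_trace <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  prov <- "experimental"; params <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    prov <- meta$provenance
    if (!is.null(meta$sds) && !is.na(meta$sds)) {
      params <- scattering_params(sds = meta$sds, s = meta$s,
                                  n = max(meta$sds, 2000L))
    }
  }
  scattering_trace(df$time_s, df$signal_au, params = params,
                   provenance = prov)
}
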