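#' LDV displacement trace
#'
#' A displacement time series as measured by a laser-Doppler-vibrometry
#' displacement decoder: a numeric vector of flagellar displacements in
#' nanometres, sampled at a fixed rate.
#'
#' @param samples numeric vector, displacement in nm; all values finite.
#' @param fs sampling rate in Hz.
#' @param t0 time offset in seconds of the first sample (default 0).
#'
#' @return An object of class `ldv_trace`: a list with elements `samples`,
#'   `fs`, `t0`.
#' @export
ldv_trace <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("trace samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (length(samples) < fs * 0.5) {
    stop("trace must be at least half a second long (", length(samples),
         " samples at fs = ", fs, " Hz)")
  }
  structure(list(samples = samples, fs = fs, t0 = t0), class = "ldv_trace")
}

#' @export
print.ldv_trace <- function(x, ...) {
  cat(sprintf("<ldv_trace> %d samples @ %g Hz (%.3f s), rms %.3g nm\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' @export
length.ldv_trace <- function(x) length(x$samples)

#' Time base of a trace
#'
#' @param trace an `ldv_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "ldv_trace"))
  trace$t0 + (seq_along(trace$samples) - 1L) / trace$fs
}

#' Duration of a trace in seconds
#' @param trace an `ldv_trace`.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$fs
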