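#' Construct a torque trace
#'
#' A sampled knee-extensor torque signal, either raw (`"nm"`) or normalized
#' to the maximal voluntary contraction (`"pct_mvc"`). The torque clock is
#' assumed synchronized with the spike clock at acquisition; `t0` allows an
#' explicit offset correction and defaults to 0.
#'
#' @param samples Numeric vector of torque samples; must be finite and
#'   non-empty.
#' @param fs Sampling rate in Hz (default 2048).
#' @param unit `"nm"` or `"pct_mvc"`.
#' @param t0 Alignment offset to the spike clock, seconds.
#' @return An object of class `torque_trace`.
#' @export
torque_trace <- function(samples, fs = 2048, unit = c("nm", "pct_mvc"),
                         t0 = 0) {
  unit <- match.arg(unit)
  samples <- as.numeric(samples)
  if (!length(samples)) stop("torque trace must be non-empty")
  if (any(!is.finite(samples))) stop("torque samples must be finite")
  stopifnot(is.numeric(fs), fs > 0)
  structure(list(samples = samples, fs = fs, unit = unit, t0 = t0),
            class = "torque_trace")
}

#' @export
print.torque_trace <- function(x, ...) {
  cat(sprintf("<torque_trace> %d samples @ %g Hz (%.4g s), unit %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$unit))
  invisible(x)
}

#' Sample times of a torque trace
#' @param x A `torque_trace`.
#' @return Times in seconds on the spike clock.
#' @export
torque_time <- function(x) {
  stopifnot(inherits(x, "torque_trace"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Zero-phase Butterworth low-pass filtering of torque
#'
#' Applies a fifth-order Butterworth low-pass filter forward and backward
#' (zero net phase, so torque-spike alignment is preserved), the standard
#' offline smoothing for dynamometer torque. The signal is extended by
#' reflection at both ends before filtering and trimmed afterwards, so
#' startup transients do not corrupt the contraction onset where recruitment
#' thresholds are read.
#'
#' @param trace A [torque_trace()].
#' @param cutoff_hz Cutoff frequency, Hz (default 10). Must be below the
#'   Nyquist frequency `fs/2`.
#' @param order Filter order (default 5).
#' @return A filtered `torque_trace` of the same length and unit.
#' @export
lowpass_torque <- function(trace, cutoff_hz = 10, order = 5) {
  stopifnot(inherits(trace, "torque_trace"))
  if (cutoff_hz >= trace$fs / 2)
    stop("cutoff must be below the Nyquist frequency (fs/2)")
  if (cutoff_hz <= 0) stop("cutoff must be positive")
  x <- trace$samples
  n <- length(x)
  bf <- signal::butter(order, 2 * cutoff_hz / trace$fs, type = "low")
  # reflective padding per end; the slowest pole pair of the Butterworth
  # rings for ~1/cutoff seconds, so a dozen of those lengths makes the
  # startup transient negligible at the trimmed boundaries
  pad <- min(n - 1L, ceiling(12 * trace$fs / cutoff_hz))
  if (pad > 0L) {
    left <- 2 * x[1] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(left, x, right)
  } else xp <- x
  yp <- rev(signal::filter(bf, rev(signal::filter(bf, xp))))
  y <- yp[(pad + 1L):(pad + n)]
  torque_trace(y, fs = trace$fs, unit = trace$unit, t0 = trace$t0)
}

#' Maximal voluntary contraction from MVC trials
#'
#' The MVC is the peak torque over the supplied maximal-effort trials
#' (conventionally two per leg), each low-pass filtered first.
#'
#' @param trials A list of [torque_trace()] objects in Nm (a single trace is
#'   also accepted).
#' @param lowpass Apply [lowpass_torque()] to each trial before taking the
#'   peak (default `TRUE`).
#' @param ... Passed to [lowpass_torque()].
#' @return An object of class `mvc_result`: list with `peak_torque` (Nm),
#'   `trial_peaks` and `source_trial` (index of the winning trial).
#' @export
compute_mvc <- function(trials, lowpass = TRUE, ...) {
  if (inherits(trials, "torque_trace")) trials <- list(trials)
  if (!length(trials)) stop("at least one MVC trial is required")
  stopifnot(all(vapply(trials, inherits, logical(1), "torque_trace")))
  peaks <- vapply(trials, function(tr) {
    if (lowpass) tr <- lowpass_torque(tr, ...)
    max(tr$samples)
  }, numeric(1))
  structure(list(peak_torque = max(peaks), trial_peaks = peaks,
                 source_trial = which.max(peaks)),
            class = "mvc_result")
}

#' @export
print.mvc_result <- function(x, ...) {
  cat(sprintf("<mvc_result> peak %.4g Nm over %d trial(s)\n",
              x$peak_torque, length(x$trial_peaks)))
  invisible(x)
}

#' Normalize a torque trace to %MVC
#'
#' @param trace A [torque_trace()] in Nm.
#' @param mvc An [compute_mvc()] result, or a positive scalar peak torque in
#'   Nm.
#' @return A `torque_trace` with `unit = "pct_mvc"`.
#' @export
normalize_torque <- function(trace, mvc) {
  stopifnot(inherits(trace, "torque_trace"))
  peak <- if (inherits(mvc, "mvc_result")) mvc$peak_torque else as.numeric(mvc)
  if (!is.finite(peak) || peak <= 0) stop("MVC peak torque must be positive")
  if (trace$unit == "pct_mvc") stop("trace is already in %MVC")
  torque_trace(100 * trace$samples / peak, fs = trace$fs, unit = "pct_mvc",
               t0 = trace$t0)
}

#' Interpolate a torque trace at arbitrary times
#'
#' Linear interpolation between samples; times outside the trace are an
#' error (the trace must span every queried instant).
#'
#' @param trace A [torque_trace()].
#' @param t Times in seconds.
#' @return Interpolated torque values.
#' @export
torque_at <- function(trace, t) {
  tt <- torque_time(trace)
  if (any(t < tt[1] - 1e-9 | t > tt[length(tt)] + 1e-9))
    stop("queried time outside the torque trace span")
  stats::approx(tt, trace$samples, xout = t, rule = 2)$y
}
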