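#' Instantaneous discharge rate series
#'
#' The instantaneous discharge rate (IDR) is the reciprocal of each
#' interspike interval, in pulses per second (pps). Each value is
#' timestamped at the later spike of its interval — the rate becomes
#' observable only once the interval closes — and no smoothing or moving
#' average is applied. Intervals spanning a long-pause segment boundary
#' (set by [remove_isi_outliers()]) produce no IDR value.
#'
#' @param train A [spike_train()] with at least 2 spikes in some segment.
#' @return An object of class `idr_series`: a data frame with columns
#'   `time` (s), `rate` (pps) and `segment`.
#' @export
compute_idr <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) < 2L)
    stop("at least 2 spikes are required to compute an IDR")
  keep <- diff(train$segment) == 0L
  if (!any(keep))
    stop("no interspike interval survives within a single segment")
  isi <- diff(train$times)[keep]
  out <- data.frame(time = train$times[-1L][keep], rate = 1 / isi,
                    segment = train$segment[-1L][keep])
  class(out) <- c("idr_series", "data.frame")
  out
}

#' Mean discharge rate over the sustained-contraction window
#'
#' The mean of the IDR values whose timestamps fall inside the analysis
#' window — by default the 15-s plateau of the ramp-hold task, taken from
#' the protocol clock (15-30 s) rather than detected from torque.
#'
#' @param train A [spike_train()] (ramp-hold protocol expected).
#' @param window Length-2 numeric window in seconds (default `c(15, 30)`).
#' @return Mean discharge rate in pps.
#' @export
mean_discharge_rate <- function(train, window = c(15, 30)) {
  idr <- compute_idr(train)
  sel <- idr$time >= window[1] & idr$time <= window[2]
  if (!any(sel))
    stop("no IDR values inside the analysis window; unit not scorable")
  mean(idr$rate[sel])
}

#' Coefficient of variation of the interspike interval
#'
#' `100 * SD(ISI) / mean(ISI)` over the analysis window, using the sample
#' (n-1) standard deviation. Intervals crossing segment boundaries are
#' excluded; an interval is attributed to the window by the timestamp of its
#' closing spike.
#'
#' @param train A [spike_train()].
#' @param window Optional length-2 window in seconds; `NULL` uses all
#'   surviving intervals.
#' @return CV of the ISI in percent.
#' @export
cv_of_isi <- function(train, window = NULL) {
  idr <- compute_idr(train)
  isi <- 1 / idr$rate
  if (!is.null(window)) isi <- isi[idr$time >= window[1] & idr$time <= window[2]]
  if (length(isi) < 3L)
    stop("at least 3 interspike intervals are required for a CV")
  100 * stats::sd(isi) / mean(isi)
}

#' Coefficient of variation of the discharge rate
#'
#' Companion of [cv_of_isi()] computed identically on the IDR values
#' (`100 * SD(rate) / mean(rate)`, sample SD). This is the quantity that
#' drives the 30% QC exclusion; the CV of the ISI is reported as an outcome.
#'
#' @inheritParams cv_of_isi
#' @return CV of the discharge rate in percent.
#' @export
cv_of_dr <- function(train, window = NULL) {
  idr <- compute_idr(train)
  rates <- idr$rate
  if (!is.null(window))
    rates <- rates[idr$time >= window[1] & idr$time <= window[2]]
  if (length(rates) < 3L)
    stop("at least 3 IDR values are required for a CV")
  100 * stats::sd(rates) / mean(rates)
}

#' Recruitment threshold of a unit
#'
#' The force, in %MVC, at the unit's first discharge: the normalized,
#' low-pass-filtered torque trace linearly interpolated at the first spike
#' time.
#'
#' @param train A [spike_train()] with at least one spike.
#' @param torque_pct A [torque_trace()] in %MVC spanning the first spike.
#' @return Recruitment threshold in %MVC.
#' @export
recruitment_threshold <- function(train, torque_pct) {
  stopifnot(inherits(train, "spike_train"), inherits(torque_pct, "torque_trace"))
  if (!length(train$times)) stop("empty spike train has no recruitment")
  if (torque_pct$unit != "pct_mvc")
    stop("torque must be normalized to %MVC first")
  torque_at(torque_pct, train$times[1])
}

#' Per-unit metrics table for one trial
#'
#' Computes the per-unit outcome measures for a set of QC-passed trains on
#' one trial: spike count, mean discharge rate (ramp-hold plateau window),
#' CV of the ISI, CV of the discharge rate, and recruitment threshold from
#' the normalized torque. Metrics that are not defined for a protocol or
#' not computable for a unit are `NA`.
#'
#' For ramp-hold trials the rate metrics use the plateau window; for
#' triangle trials `mean_dr_pps` is left `NA` (the task has no sustained
#' phase) and the CVs use the unit's full discharge span.
#'
#' @param units List of QC-passed [spike_train()] objects.
#' @param torque_pct Normalized, filtered [torque_trace()] for the trial.
#' @param sex Optional subject sex carried into the table.
#' @param hold_window Plateau window for ramp-hold metrics (default
#'   `c(15, 30)` s).
#' @return A data frame with columns `subject_id`, `sex`, `side`,
#'   `protocol`, `unit_id`, `n_spikes`, `mean_dr_pps`, `cv_isi_pct`,
#'   `cv_dr_pct`, `rt_pct_mvc`.
#' @export
unit_metrics <- function(units, torque_pct, sex = NA_character_,
                         hold_window = c(15, 30)) {
  if (inherits(units, "spike_train")) units <- list(units)
  rows <- lapply(units, function(u) {
    hold <- u$protocol == "ramp_hold"
    win <- if (hold) hold_window else NULL
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    data.frame(
      subject_id = u$subject_id, sex = sex, side = u$side,
      protocol = u$protocol, unit_id = u$unit_id,
      n_spikes = length(u$times),
      mean_dr_pps = if (hold) safe(mean_discharge_rate(u, hold_window))
                    else NA_real_,
      cv_isi_pct = safe(cv_of_isi(u, win)),
      cv_dr_pct = safe(cv_of_dr(u, win)),
      rt_pct_mvc = safe(recruitment_threshold(u, torque_pct)),
      stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}
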