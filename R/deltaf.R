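#' Smooth an IDR profile with support vector regression
#'
#' Fits epsilon-insensitive support vector regression (Gaussian radial
#' kernel) to the (time, IDR) points of one unit and evaluates the fit on a
#' uniform grid restricted to the unit's active span (first to last spike).
#' SVR is robust to the occasional aberrant interval in decomposed trains,
#' which is why it is preferred over polynomial fits for discharge-rate
#' profiles feeding the delta-F computation. Negative predictions are
#' clipped to zero.
#'
#' Hyperparameter defaults: kernel width (`sigma_s`) 2 s — several
#' interspike intervals at physiological rates, so the fit tracks rate
#' modulation without chasing single intervals; `epsilon` 0.2 pps — near the
#' quantization scale of IDR values; regularization `cost` 10. All three are
#' recorded in the returned object.
#'
#' @param idr An `idr_series` from [compute_idr()] with at least 10 points.
#' @param grid_step_s Evaluation grid step in seconds (default 0.01).
#' @param sigma_s Gaussian kernel width in seconds.
#' @param epsilon Epsilon-insensitive tube half-width, pps.
#' @param cost Regularization weight.
#' @return An object of class `smoothed_rate`: list with `time` (grid, s),
#'   `rate` (pps), `span` (active span), `residual_rms` (pps, fit residuals
#'   at the data points), `degenerate` (all residuals at the epsilon bound)
#'   and `hyperparameters`.
#' @export
smooth_idr_svr <- function(idr, grid_step_s = 0.01, sigma_s = 2,
                           epsilon = 0.2, cost = 10) {
  stopifnot(inherits(idr, "idr_series"))
  if (nrow(idr) < 10L)
    stop("at least 10 IDR points are required for SVR smoothing")
  stopifnot(grid_step_s > 0, sigma_s > 0, epsilon >= 0, cost > 0)
  fit <- e1071::svm(x = matrix(idr$time, ncol = 1), y = idr$rate,
                    type = "eps-regression", kernel = "radial",
                    gamma = 1 / (2 * sigma_s^2), cost = cost,
                    epsilon = epsilon, scale = FALSE, fitted = FALSE)
  span <- range(idr$time)
  grid <- seq(span[1], span[2], by = grid_step_s)
  if (grid[length(grid)] < span[2]) grid <- c(grid, span[2])
  if (fit$tot.nSV == 0L) {
    # every observation already lies inside the epsilon tube of a constant:
    # the flattest such function is the midrange of the data
    const <- (min(idr$rate) + max(idr$rate)) / 2
    resid <- idr$rate - const
    rate <- rep(max(0, const), length(grid))
  } else {
    resid <- idr$rate -
      as.numeric(stats::predict(fit, matrix(idr$time, ncol = 1)))
    rate <- pmax(0, as.numeric(stats::predict(fit, matrix(grid, ncol = 1))))
  }
  structure(
    list(time = grid, rate = rate, span = span,
         residual_rms = sqrt(mean(resid^2)),
         degenerate = all(abs(abs(resid) - epsilon) < 1e-8),
         hyperparameters = list(grid_step_s = grid_step_s, sigma_s = sigma_s,
                                epsilon = epsilon, cost = cost)),
    class = "smoothed_rate"
  )
}

#' Evaluate a smoothed rate profile at arbitrary times
#'
#' Linear interpolation between grid values; times outside the unit's active
#' span are an error.
#'
#' @param sm A `smoothed_rate`.
#' @param t Times in seconds.
#' @return Smoothed rate(s) in pps.
#' @export
smoothed_rate_at <- function(sm, t) {
  stopifnot(inherits(sm, "smoothed_rate"))
  if (any(t < sm$span[1] - 1e-9 | t > sm$span[2] + 1e-9))
    stop("queried time outside the unit's active span")
  stats::approx(sm$time, sm$rate, xout = t, rule = 2)$y
}

#' @export
print.smoothed_rate <- function(x, ...) {
  cat(sprintf("<smoothed_rate> %.3f-%.3f s, residual RMS %.3g pps\n",
              x$span[1], x$span[2], x$residual_rms))
  invisible(x)
}

#' Delta-F of one reporter/test pair
#'
#' The onset-offset hysteresis of a higher-threshold (test) unit measured on
#' the smoothed discharge rate of a lower-threshold (reporter) unit:
#'
#' \deqn{\Delta F = f_{reporter}(t_{rec}^{test}) -
#'                  f_{reporter}(t_{derec}^{test})}
#'
#' where the test unit's recruitment and derecruitment are its first and
#' last surviving spikes — the observable proxies for the state
#' transitions — and `f_reporter` is the SVR-smoothed reporter rate
#' (grid values, linearly interpolated). A positive delta-F indicates that
#' the reporter needed less drive to sustain the test unit's discharge at
#' derecruitment than at recruitment, the signature of a persistent inward
#' current.
#'
#' @param reporter_sm The reporter's `smoothed_rate`.
#' @param test_on,test_off Test unit recruitment and derecruitment times
#'   (s); both must lie inside the reporter's active span.
#' @return Delta-F in pps.
#' @export
pair_delta_f <- function(reporter_sm, test_on, test_off) {
  stopifnot(inherits(reporter_sm, "smoothed_rate"), test_on < test_off)
  if (test_on < reporter_sm$span[1] - 1e-9 ||
      test_off > reporter_sm$span[2] + 1e-9)
    stop("test unit's discharge span is not covered by the reporter")
  smoothed_rate_at(reporter_sm, test_on) - smoothed_rate_at(reporter_sm, test_off)
}

#' Enumerate and score reporter/test pairs on one triangle trial
#'
#' Every ordered pair with `RT_reporter < RT_test` is evaluated against the
#' three inclusion criteria of the paired-motor-unit analysis:
#'
#' 1. recruitment gap: the test unit is recruited at least `min_gap_s`
#'    (default 1 s) after the reporter, guaranteeing full PIC activation in
#'    the reporter;
#' 2. rate-rate correlation: the Pearson correlation of the two smoothed
#'    rate profiles, resampled on the common activity grid, is at least
#'    `min_r` (default 0.7), evidence of shared synaptic drive;
#' 3. reporter modulation: the reporter's smoothed rate spans at least
#'    `min_range_pps` (default 0.5 pps) while the test unit is active.
#'
#' All three thresholds are inclusive ("at least"). Delta-F is computed for
#' every pair whose test span is covered by the reporter, but only pairs
#' passing all three criteria are flagged `accepted`.
#'
#' @param units QC-passed [spike_train()] list for one triangle trial
#'   (>= 2 units).
#' @param torque_pct Normalized [torque_trace()] used for recruitment
#'   thresholds (pair ordering).
#' @param min_gap_s,min_r,min_range_pps Inclusion thresholds.
#' @param grid_step_s,sigma_s,epsilon,cost Passed to [smooth_idr_svr()].
#' @return An object of class `pair_table`: a data frame with one row per
#'   candidate pair (`reporter_id`, `test_id`, `rt_reporter`, `rt_test`,
#'   `recruit_gap_s`, `rate_rate_r`, `reporter_range_pps`, `delta_f_pps`,
#'   `accepted`, `reject_reason`), with the per-unit smoothed profiles in
#'   attribute `"smoothed"`.
#' @export
enumerate_pairs <- function(units, torque_pct, min_gap_s = 1.0, min_r = 0.7,
                            min_range_pps = 0.5, grid_step_s = 0.01,
                            sigma_s = 2, epsilon = 0.2, cost = 10) {
  if (inherits(units, "spike_train")) units <- list(units)
  empty <- data.frame(reporter_id = character(), test_id = character(),
                      rt_reporter = numeric(), rt_test = numeric(),
                      recruit_gap_s = numeric(), rate_rate_r = numeric(),
                      reporter_range_pps = numeric(), delta_f_pps = numeric(),
                      accepted = logical(), reject_reason = character(),
                      stringsAsFactors = FALSE)
  usable <- Filter(function(u) length(u$times) >= 11L, units)
  if (length(usable) < 2L)
    return(structure(empty, smoothed = list(), class = c("pair_table",
                                                         "data.frame")))
  ids <- vapply(usable, function(u) u$unit_id, character(1))
  rt <- vapply(usable, recruitment_threshold, numeric(1),
               torque_pct = torque_pct)
  first <- vapply(usable, function(u) u$times[1], numeric(1))
  last <- vapply(usable, function(u) u$times[length(u$times)], numeric(1))
  sm <- lapply(usable, function(u)
    smooth_idr_svr(compute_idr(u), grid_step_s = grid_step_s,
                   sigma_s = sigma_s, epsilon = epsilon, cost = cost))
  names(sm) <- ids
  rows <- list()
  for (i in seq_along(usable)) for (j in seq_along(usable)) {
    if (i == j || rt[i] >= rt[j]) next     # reporter must have the lower RT
    gap <- first[j] - first[i]
    covered <- first[j] >= sm[[i]]$span[1] - 1e-9 &&
               last[j] <= sm[[i]]$span[2] + 1e-9
    # correlation on the overlap of both units' active spans
    lo <- max(sm[[i]]$span[1], sm[[j]]$span[1])
    hi <- min(sm[[i]]$span[2], sm[[j]]$span[2])
    r <- NA_real_
    if (hi - lo > 2 * grid_step_s) {
      g <- seq(lo, hi, by = grid_step_s)
      r <- suppressWarnings(stats::cor(smoothed_rate_at(sm[[i]], g),
                                       smoothed_rate_at(sm[[j]], g)))
    }
    rng <- if (covered) {
      g <- seq(first[j], last[j], by = grid_step_s)
      vals <- smoothed_rate_at(sm[[i]], g)
      max(vals) - min(vals)
    } else NA_real_
    df <- if (covered) pair_delta_f(sm[[i]], first[j], last[j]) else NA_real_
    fail <- character(0)
    if (!covered) fail <- c(fail, "coverage")
    if (gap < min_gap_s) fail <- c(fail, "recruit_gap")
    if (is.na(r) || r < min_r) fail <- c(fail, "rate_rate_r")
    if (is.na(rng) || rng < min_range_pps) fail <- c(fail, "reporter_range")
    rows[[length(rows) + 1L]] <- data.frame(
      reporter_id = ids[i], test_id = ids[j],
      rt_reporter = rt[i], rt_test = rt[j],
      recruit_gap_s = gap, rate_rate_r = r, reporter_range_pps = rng,
      delta_f_pps = df, accepted = !length(fail),
      reject_reason = paste(fail, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) rbind_rows(rows)
         else empty
  structure(out, smoothed = sm, class = c("pair_table", "data.frame"))
}

#' Unit-wise delta-F
#'
#' Collapses the pair table to one delta-F per test unit: the arithmetic
#' mean over all accepted reporter pairings. Test units with no accepted
#' pair are absent from the result.
#'
#' @param pairs A `pair_table` from [enumerate_pairs()].
#' @return A data frame with `test_id`, `delta_f_pps`, `n_reporters`.
#' @export
unitwise_delta_f <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  acc <- pairs[pairs$accepted & !is.na(pairs$delta_f_pps), , drop = FALSE]
  if (!nrow(acc))
    return(data.frame(test_id = character(), delta_f_pps = numeric(),
                      n_reporters = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(delta_f_pps ~ test_id, data = acc, FUN = mean)
  cnt <- stats::aggregate(cbind(n_reporters = delta_f_pps) ~ test_id,
                          data = acc, FUN = length)
  out <- merge(agg, cnt, by = "test_id", sort = TRUE)
  out$n_reporters <- as.integer(out$n_reporters)
  out
}

#' Delta-F analysis of one triangle trial
#'
#' Convenience wrapper: QC'd units plus normalized torque in, pair-level and
#' unit-level delta-F tables out.
#'
#' @inheritParams enumerate_pairs
#' @return A list with `pairs` (pair table) and `units` (unit-wise table,
#'   with trial provenance columns prepended).
#' @export
deltaf_trial <- function(units, torque_pct, min_gap_s = 1.0, min_r = 0.7,
                         min_range_pps = 0.5, grid_step_s = 0.01,
                         sigma_s = 2, epsilon = 0.2, cost = 10) {
  if (inherits(units, "spike_train")) units <- list(units)
  pairs <- enumerate_pairs(units, torque_pct, min_gap_s = min_gap_s,
                           min_r = min_r, min_range_pps = min_range_pps,
                           grid_step_s = grid_step_s, sigma_s = sigma_s,
                           epsilon = epsilon, cost = cost)
  uw <- unitwise_delta_f(pairs)
  if (length(units) && nrow(uw)) {
    uw <- cbind(subject_id = units[[1]]$subject_id, side = units[[1]]$side,
                uw, stringsAsFactors = FALSE)
  }
  list(pairs = pairs, units = uw)
}
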