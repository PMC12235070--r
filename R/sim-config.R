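#' Configuration for the synthetic motoneuron pool
#'
#' Defines a phenomenological pool of motor units driven by a common drive
#' equal to the commanded force trajectory (in %MVC). Each unit `i` has a
#' recruitment threshold `RT_i`, a rate gain `g_i` (pps per %MVC), a peak
#' discharge rate implementing onion-skin rate coding, and a persistent
#' inward current (PIC) hysteresis amplitude `P_i` expressed in %MVC of
#' equivalent drive. The unit is silent until the drive reaches `RT_i`; once
#' recruited the PIC adds `P_i` to the effective drive instantaneously, so
#' the unit derecruits only when the drive falls below `RT_i - P_i`. This
#' step model yields a closed-form onset-offset hysteresis for every
#' reporter/test pair: `deltaF_true = g_reporter * P_test` (see
#' [ground_truth()]), which downstream estimators are validated against.
#'
#' Recruitment thresholds are spaced evenly over `rt_range`, and the gain
#' decreases linearly from `max(gain_range)` for the lowest-threshold unit to
#' `min(gain_range)` for the highest, so that low-threshold units modulate
#' their rate more steeply. The discharge-rate ceiling follows
#' `peak_rate_a - peak_rate_b * RT_i` (clipped at `rate_min`), reproducing
#' the onion-skin pattern in which earlier-recruited units discharge faster.
#'
#' @param n_units Number of motor units in the pool (>= 1).
#' @param rt_range Length-2 numeric, low/high recruitment thresholds in
#'   %MVC, within \[0, 100\] with `rt_range[1] < rt_range[2]`.
#' @param rate_min Discharge rate at recruitment, pps.
#' @param gain_range Length-2 numeric, rate gain in pps per %MVC. The larger
#'   value is assigned to the lowest-threshold unit.
#' @param peak_rate_a,peak_rate_b Onion-skin ceiling parameters: the peak
#'   rate of unit `i` is `peak_rate_a - peak_rate_b * RT_i`, clipped to be
#'   at least `rate_min`.
#' @param pic_amplitude PIC hysteresis `P_i` in %MVC; a scalar recycled to
#'   all units or a vector of length `n_units`. `0` disables the PIC.
#' @param isi_cv Target coefficient of variation of the interspike interval
#'   (dimensionless, >= 0); `0` gives a noiseless renewal process.
#' @param fs Torque sampling rate, Hz.
#' @param torque_noise_sd Additive Gaussian torque noise, %MVC.
#' @param pnr_db_range Range of per-unit pulse-to-noise ratios (dB) assigned
#'   uniformly at random; the default keeps every unit above the 30 dB
#'   quality gate.
#' @param inject_artifacts If `TRUE`, a doublet (extra spike 20 ms after a
#'   randomly chosen discharge) and a pause (deletion of spikes in a 300 ms
#'   window) are injected into each train; used only to exercise the QC
#'   filters.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trial()], [ground_truth()], [unit_rate()]
#' @export
sim_config <- function(n_units = 10,
                       rt_range = c(3, 21),
                       rate_min = 8,
                       gain_range = c(0.4, 0.6),
                       peak_rate_a = 35,
                       peak_rate_b = 0.25,
                       pic_amplitude = 5,
                       isi_cv = 0.10,
                       fs = 2048,
                       torque_noise_sd = 0.25,
                       pnr_db_range = c(32, 46),
                       inject_artifacts = FALSE) {
  stopifnot(is.numeric(n_units), length(n_units) == 1L, n_units >= 1,
            n_units == round(n_units))
  stopifnot(length(rt_range) == 2L, rt_range[1] >= 0, rt_range[2] <= 100,
            rt_range[1] < rt_range[2])
  stopifnot(rate_min > 0, length(gain_range) == 2L, all(gain_range > 0))
  stopifnot(isi_cv >= 0, fs > 0, torque_noise_sd >= 0)
  pic <- rep_len(as.numeric(pic_amplitude), n_units)
  if (any(pic < 0)) stop("pic_amplitude must be nonnegative")
  cfg <- list(n_units = as.integer(n_units), rt_range = as.numeric(rt_range),
              rate_min = rate_min, gain_range = as.numeric(gain_range),
              peak_rate_a = peak_rate_a, peak_rate_b = peak_rate_b,
              pic_amplitude = pic, isi_cv = isi_cv, fs = fs,
              torque_noise_sd = torque_noise_sd,
              pnr_db_range = as.numeric(pnr_db_range),
              inject_artifacts = isTRUE(inject_artifacts))
  class(cfg) <- "sim_config"
  # the ceiling must leave headroom above the recruitment rate
  pars <- unit_params(cfg)
  if (any(pars$peak_rate <= cfg$rate_min))
    stop("rate ceiling <= rate_min for at least one unit; ",
         "adjust peak_rate_a/peak_rate_b or rate_min")
  cfg
}

#' Per-unit parameters implied by a simulator configuration
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per unit: `unit_id`, `rt` (%MVC),
#'   `gain` (pps/%MVC), `peak_rate` (pps), `pic` (%MVC).
#' @export
unit_params <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_units
  rt <- if (n == 1L) mean(config$rt_range) else
    seq(config$rt_range[1], config$rt_range[2], length.out = n)
  g_hi <- max(config$gain_range); g_lo <- min(config$gain_range)
  frac <- if (n == 1L) 0 else (rt - rt[1]) / (rt[n] - rt[1])
  gain <- g_hi - (g_hi - g_lo) * frac
  peak <- pmax(config$peak_rate_a - config$peak_rate_b * rt, config$rate_min)
  data.frame(unit_id = sprintf("MU%02d", seq_len(n)), rt = rt, gain = gain,
             peak_rate = peak, pic = config$pic_amplitude,
             stringsAsFactors = FALSE)
}

#' Analytic ground truth of a simulated pool
#'
#' For every ordered (reporter, test) pair with `RT_reporter < RT_test`, the
#' step-PIC model implies an onset-offset hysteresis of exactly
#' `deltaF_true = g_reporter * P_test` pps, provided the reporter stays below
#' its rate ceiling at both of the test unit's state transitions. Pairs where
#' the ceiling would clip the reporter at either transition are flagged.
#'
#' @param config A [sim_config()].
#' @param drive_max Largest drive reached by the protocol (%MVC), used only
#'   for the ceiling check. Default 30.
#' @return A list with `units` (the [unit_params()] table) and `pairs`, a
#'   data frame with `reporter_id`, `test_id`, `deltaf_true` (pps),
#'   `ceiling_clipped` (logical) and `covered` (logical: the reporter is
#'   still discharging when the test unit derecruits, so the pair is
#'   estimable).
#' @export
ground_truth <- function(config, drive_max = 30) {
  units <- unit_params(config)
  n <- nrow(units)
  if (n < 2L) {
    pairs <- data.frame(reporter_id = character(), test_id = character(),
                        deltaf_true = numeric(), ceiling_clipped = logical())
    return(list(units = units, pairs = pairs))
  }
  idx <- which(outer(units$rt, units$rt, "<"), arr.ind = TRUE)
  rep_i <- idx[, 1]; test_i <- idx[, 2]
  # reporter rate (unclipped) at test recruitment and derecruitment drives
  d_on <- units$rt[test_i]                        # ascending: drive = RT_test
  d_off <- units$rt[test_i] - units$pic[test_i]   # descending crossing
  r_on <- config$rate_min + units$gain[rep_i] *
    (d_on + units$pic[rep_i] - units$rt[rep_i])
  r_off <- config$rate_min + units$gain[rep_i] *
    (d_off + units$pic[rep_i] - units$rt[rep_i])
  clipped <- r_on > units$peak_rate[rep_i] | r_off > units$peak_rate[rep_i]
  # the reporter must still be recruited when the test unit derecruits
  covered <- d_off >= units$rt[rep_i] - units$pic[rep_i]
  pairs <- data.frame(reporter_id = units$unit_id[rep_i],
                      test_id = units$unit_id[test_i],
                      deltaf_true = units$gain[rep_i] * units$pic[test_i],
                      ceiling_clipped = clipped,
                      covered = covered,
                      stringsAsFactors = FALSE)
  ord <- order(pairs$test_id, pairs$reporter_id)
  list(units = units, pairs = pairs[ord, , drop = FALSE])
}

#' Validation pool for the delta-F estimator
#'
#' A frozen 10-unit configuration used to validate delta-F recovery against
#' ground truth. All gains are 0.5 pps/%MVC so that each test unit's true
#' delta-F is `0.5 * P_i`; PIC amplitudes of 2, 4, 6 and 8 %MVC inject true
#' delta-F levels of 1-4 pps, each carried by two test units. The two
#' lowest-threshold units get a small PIC (1 %MVC) so they act as reporters
#' that keep discharging well past every test unit's derecruitment, and PIC
#' amplitudes increase with recruitment threshold within each half of the
#' pool so that derecruitment drives are staggered — pairs are either
#' cleanly covered or cleanly rejected rather than ending at a reporter's
#' span edge.
#'
#' @param pic_scale Multiplier on all PIC amplitudes; `0` gives the matched
#'   null pool (no hysteresis anywhere, true delta-F identically zero).
#' @param isi_cv Interspike-interval variability (default 0.10).
#' @return A [sim_config()].
#' @export
deltaf_validation_config <- function(pic_scale = 1, isi_cv = 0.10) {
  sim_config(n_units = 10, rt_range = c(3, 21), gain_range = c(0.5, 0.5),
             pic_amplitude = pic_scale * c(1, 1, 2, 4, 6, 8, 2, 4, 6, 8),
             isi_cv = isi_cv)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d units, RT %.3g-%.3g %%MVC, ",
                     "isi_cv = %.3g, fs = %g Hz\n"),
              x$n_units, x$rt_range[1], x$rt_range[2], x$isi_cv, x$fs))
  invisible(x)
}
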