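#' Instantaneous discharge rate of one simulated unit
#'
#' Implements the pool's rate model. A unit is silent while its effective
#' drive — the common drive plus, once recruited, the PIC contribution
#' `P_i` — is below its recruitment threshold `RT_i`. Above threshold the
#' rate rises linearly from `rate_min` with gain `g_i` and saturates at the
#' unit's onion-skin ceiling:
#'
#' \deqn{r(D) = \min(rate_{min} + g_i (D_{eff} - RT_i),\; peak_i), \quad
#'       D_{eff} = D + P_i \cdot [recruited]}
#'
#' Because the PIC only contributes after recruitment, the unit recruits when
#' the drive reaches `RT_i` but derecruits when it falls below `RT_i - P_i`:
#' the hysteresis that the paired-unit delta-F method estimates.
#'
#' @param drive_pct Common drive in %MVC (vectorized); must be >= 0.
#' @param unit One row of [unit_params()] (list or single-row data frame with
#'   `rt`, `gain`, `peak_rate`, `pic`).
#' @param recruited Logical: has the unit already been recruited (PIC
#'   active)?
#' @param rate_min Discharge rate at recruitment, pps.
#' @return Discharge rate(s) in pps (0 when below threshold).
#' @export
unit_rate <- function(drive_pct, unit, recruited = FALSE, rate_min = 8) {
  if (any(drive_pct < 0)) stop("drive must be nonnegative")
  d_eff <- drive_pct + if (isTRUE(recruited)) unit$pic else 0
  r <- ifelse(d_eff < unit$rt, 0,
              pmin(rate_min + unit$gain * (d_eff - unit$rt), unit$peak_rate))
  as.numeric(r)
}

# Renewal-process discharge times for one unit over one protocol.
# The instantaneous mean ISI is 1/rate evaluated at the current spike time;
# each ISI is perturbed multiplicatively by 1 + isi_cv * Z, Z ~ N(0,1),
# floored at 0.05 to keep intervals positive.
simulate_unit_spikes <- function(unit, profile, config) {
  rt <- unit$rt
  if (rt > profile$plateau) return(numeric(0))
  on_idx <- which(profile$target >= rt)
  if (!length(on_idx)) return(numeric(0))
  t <- profile$time[on_idx[1]]
  t_end <- profile$duration
  spikes <- numeric(512)
  n <- 0L
  repeat {
    n <- n + 1L
    if (n > length(spikes)) spikes <- c(spikes, numeric(length(spikes)))
    spikes[n] <- t
    d_eff <- profile_at(profile, t) + unit$pic
    rate <- min(config$rate_min + unit$gain * (d_eff - rt), unit$peak_rate)
    if (rate <= 0) break
    mult <- max(0.05, 1 + config$isi_cv * stats::rnorm(1L))
    t_next <- t + mult / rate
    if (t_next > t_end) break
    if (profile_at(profile, t_next) + unit$pic < rt) break  # derecruited
    t <- t_next
  }
  spikes[seq_len(n)]
}

# Optional artifact injection for QC-filter testing: one doublet (extra
# spike 20 ms after a mid-train discharge) and one long pause (spikes in a
# 300 ms window deleted).
inject_artifacts <- function(times) {
  if (length(times) < 10L) return(times)
  k <- sample(seq(3L, length(times) - 3L), 1L)
  times <- sort(unique(c(times, times[k] + 0.020)))
  j <- sample(seq(3L, length(times) - 3L), 1L)
  gap <- times >= times[j] & times < times[j] + 0.300
  gap[j] <- FALSE
  times[!gap]
}

#' Simulate one contraction trial of a motoneuron pool
#'
#' Draws discharge times for every unit in the pool by a renewal process
#' whose instantaneous mean interspike interval tracks the reciprocal of the
#' unit's model rate (see [unit_rate()]), perturbed multiplicatively by
#' zero-mean Gaussian noise with coefficient of variation `isi_cv`. The
#' torque trace equals the commanded profile plus additive Gaussian noise.
#' Identical `(config, profile, seed)` triples reproduce identical output.
#'
#' @param config A [sim_config()].
#' @param profile A [generate_protocol()] target profile.
#' @param seed Integer RNG seed.
#' @param subject_id,side Metadata stamped on the generated trains.
#' @return An object of class `mu_trial`: a list with `spikes` (list of
#'   [spike_train()]), `torque` (a [torque_trace()] in %MVC), `truth`
#'   (the [ground_truth()] tables), `config`, `profile` and `seed`.
#' @examples
#' cfg <- sim_config(n_units = 4, isi_cv = 0, fs = 256)
#' trial <- simulate_trial(cfg, generate_protocol("triangle", 30, fs = 256),
#'                         seed = 1)
#' sapply(trial$spikes, n_spikes)
#' @export
simulate_trial <- function(config, profile, seed = 1L,
                           subject_id = "S01", side = "more_affected") {
  stopifnot(inherits(config, "sim_config"), inherits(profile, "target_profile"))
  set.seed(as.integer(seed))
  units <- unit_params(config)
  pnr <- stats::runif(config$n_units, config$pnr_db_range[1],
                      config$pnr_db_range[2])
  trains <- vector("list", config$n_units)
  for (i in seq_len(config$n_units)) {
    times <- simulate_unit_spikes(units[i, ], profile, config)
    if (config$inject_artifacts) times <- inject_artifacts(times)
    trains[[i]] <- spike_train(times, unit_id = units$unit_id[i],
                               subject_id = subject_id, side = side,
                               protocol = profile$kind, pnr_db = pnr[i])
  }
  names(trains) <- units$unit_id
  torque_pct <- profile$target +
    stats::rnorm(length(profile$target), 0, config$torque_noise_sd)
  torque <- torque_trace(torque_pct, fs = profile$fs, unit = "pct_mvc")
  structure(
    list(spikes = trains, torque = torque,
         truth = ground_truth(config, drive_max = profile$plateau),
         config = config, profile = profile, seed = as.integer(seed),
         subject_id = subject_id, side = side),
    class = "mu_trial"
  )
}

#' @export
print.mu_trial <- function(x, ...) {
  cat(sprintf("<mu_trial> %s/%s %s: %d units, seed %d\n",
              x$subject_id, x$side, x$profile$kind, length(x$spikes), x$seed))
  invisible(x)
}
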