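# Shared fixtures, all generated in code.

# deterministic spike times following an instantaneous rate function:
# next spike = current + 1 / rate(current)
spikes_from_rate <- function(rate_fn, t0 = 0, t_end = 30) {
  t <- t0
  out <- numeric(0)
  repeat {
    r <- rate_fn(t)
    if (!is.finite(r) || r <= 0) break
    out <- c(out, t)
    t_next <- t + 1 / r
    if (t_next > t_end) break
    t <- t_next
  }
  out
}

# linear %MVC ramp torque trace covering [0, t_end]
ramp_torque <- function(rate_pct_s = 2, t_end = 30, fs = 256,
                        peak = 30) {
  tt <- seq(0, t_end, by = 1 / fs)
  pct <- pmin(rate_pct_s * tt, peak)
  half <- tt > t_end / 2
  pct[half] <- pmax(0, peak - rate_pct_s * (tt[half] - t_end / 2))
  torque_trace(pct, fs = fs, unit = "pct_mvc")
}

# a hand-made smoothed_rate object for direct pair_delta_f tests
fake_smoothed <- function(time, rate) {
  structure(list(time = time, rate = rate, span = range(time),
                 residual_rms = 0, degenerate = FALSE,
                 hyperparameters = list()),
            class = "smoothed_rate")
}

# small fast pool used by several behavioural tests
small_config <- function(...) {
  args <- list(n_units = 4, rt_range = c(4, 16), gain_range = c(0.5, 0.5),
               pic_amplitude = 2, isi_cv = 0, fs = 256,
               torque_noise_sd = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# analytic instantaneous rate of one simulated unit under a profile
analytic_rate <- function(t, unit, profile, rate_min = 8) {
  d <- profile_at(profile, t) + unit$pic
  ifelse(d < unit$rt, 0,
         pmin(rate_min + unit$gain * (d - unit$rt), unit$peak_rate))
}
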