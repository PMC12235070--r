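#' Build a target force profile for an isometric contraction task
#'
#' Constructs the commanded torque trajectory, in percent of maximal voluntary
#' contraction (%MVC), for one of the two submaximal knee-extension tasks used
#' throughout the package:
#'
#' * `"ramp_hold"` — ramp up to the plateau in 15 s, hold for 15 s, ramp back
#'   down in 15 s (45 s total at the default plateau of 30 %MVC).
#' * `"triangle"` — ramp up at a fixed rate of 2 %MVC/s to the peak and
#'   immediately back down at the same rate (30 s total at 30 %MVC).
#'
#' Profiles are piecewise linear, start and end at rest (0 %MVC), and are
#' sampled at the torque acquisition rate.
#'
#' @param kind Either `"ramp_hold"` or `"triangle"`.
#' @param plateau_pct Plateau (or triangle peak) level in %MVC, in (0, 100].
#' @param fs Sampling rate in Hz (default 2048, the acquisition rate).
#' @param ramp_up_s,hold_s,ramp_down_s Segment durations in seconds for the
#'   ramp-hold task. Ignored for the triangle task, whose durations follow
#'   from `ramp_rate`.
#' @param ramp_rate Ramp rate in %MVC/s for the triangle task (default 2).
#' @return An object of class `target_profile`: a list with elements `kind`,
#'   `plateau`, `ramp_rate`, `durations` (named segment durations, s),
#'   `duration` (total, s), `fs`, `time` (sample times, s) and `target`
#'   (%MVC at each sample).
#' @examples
#' prof <- generate_protocol("triangle", 30, fs = 256)
#' profile_at(prof, 15) # peak, 30 %MVC
#' @export
generate_protocol <- function(kind = c("ramp_hold", "triangle"),
                              plateau_pct = 30, fs = 2048,
                              ramp_up_s = 15, hold_s = 15, ramp_down_s = 15,
                              ramp_rate = 2) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(plateau_pct), length(plateau_pct) == 1L,
            plateau_pct > 0, plateau_pct <= 100,
            is.numeric(fs), fs > 0)
  if (kind == "ramp_hold") {
    durations <- c(ramp_up = ramp_up_s, hold = hold_s, ramp_down = ramp_down_s)
    knots_t <- cumsum(c(0, durations))
    knots_y <- c(0, plateau_pct, plateau_pct, 0)
    rate <- plateau_pct / ramp_up_s
  } else {
    leg <- plateau_pct / ramp_rate
    durations <- c(ramp_up = leg, ramp_down = leg)
    knots_t <- cumsum(c(0, durations))
    knots_y <- c(0, plateau_pct, 0)
    rate <- ramp_rate
  }
  duration <- sum(durations)
  time <- seq(0, duration, by = 1 / fs)
  target <- stats::approx(knots_t, knots_y, xout = time, rule = 2)$y
  structure(
    list(kind = kind, plateau = plateau_pct, ramp_rate = rate,
         durations = durations, duration = duration, fs = fs,
         knots_t = knots_t, knots_y = knots_y,
         time = time, target = target),
    class = "target_profile"
  )
}

#' Evaluate a target profile at arbitrary times
#'
#' Linear interpolation of the commanded %MVC trajectory; times outside the
#' trial are clamped to the endpoint values (0 %MVC).
#'
#' @param profile A `target_profile`.
#' @param t Numeric vector of times in seconds.
#' @return %MVC values at `t`.
#' @export
profile_at <- function(profile, t) {
  stopifnot(inherits(profile, "target_profile"))
  stats::approx(profile$knots_t, profile$knots_y, xout = t, rule = 2)$y
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("<target_profile> %s: %.4g %%MVC peak, %.4g s, fs = %g Hz\n",
              x$kind, x$plateau, x$duration, x$fs))
  invisible(x)
}
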