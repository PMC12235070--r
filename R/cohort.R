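#' Simulate a two-sided patient cohort
#'
#' Generates a full study's worth of trials: for every subject, both body
#' sides, and both contraction protocols (ramp-hold for discharge metrics,
#' triangle for the delta-F analysis). Disease asymmetry and its sex
#' dependence are injected by scaling each side's PIC amplitude and rate
#' gain relative to the base configuration: the more-affected side gets a
#' reduced PIC (lower delta-F) and an elevated gain (higher discharge rate),
#' with both effects larger in females. The default scalings emulate the
#' qualitative pattern of marked female lateralization; they are study
#' conditions, not fitted quantities.
#'
#' @param n_female,n_male Number of subjects per sex.
#' @param config Base [sim_config()] shared by all trials.
#' @param pic_scale,gain_scale Named numeric vectors with entries
#'   `female_more`, `female_less`, `male_more`, `male_less`: multipliers on
#'   `pic_amplitude` and on `gain_range`.
#' @param updrs_mean,updrs_sd UPDRS Part III scores drawn per subject
#'   (rounded, floored at 1).
#' @param mvc_mean,mvc_sd Subject MVC in Nm (floored at 20).
#' @param seed Integer seed; trial seeds are derived deterministically from
#'   it.
#' @return A list of class `mu_cohort`: `subjects` (data frame with
#'   `subject_id`, `sex`, `updrs_iii`, `mvc_nm`) and `trials` (list; each
#'   element a [simulate_trial()] result with `sex` and ground truth
#'   attached).
#' @export
simulate_cohort <- function(n_female = 14, n_male = 13,
                            config = sim_config(),
                            pic_scale = c(female_more = 0.25,
                                          female_less = 1,
                                          male_more = 0.75,
                                          male_less = 1),
                            gain_scale = c(female_more = 1.2,
                                           female_less = 1,
                                           male_more = 1.05,
                                           male_less = 1),
                            updrs_mean = 11, updrs_sd = 4,
                            mvc_mean = 55, mvc_sd = 12,
                            seed = 1L) {
  stopifnot(n_female >= 1, n_male >= 1, inherits(config, "sim_config"))
  need <- c("female_more", "female_less", "male_more", "male_less")
  stopifnot(all(need %in% names(pic_scale)), all(need %in% names(gain_scale)))
  set.seed(as.integer(seed))
  n <- n_female + n_male
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    sex = rep(c("female", "male"), c(n_female, n_male)),
    updrs_iii = pmax(1, round(stats::rnorm(n, updrs_mean, updrs_sd))),
    mvc_nm = pmax(20, stats::rnorm(n, mvc_mean, mvc_sd)),
    stringsAsFactors = FALSE)
  trial_seeds <- sample.int(.Machine$integer.max, n * 4L)
  profiles <- list(ramp_hold = generate_protocol("ramp_hold", 30, config$fs),
                   triangle = generate_protocol("triangle", 30, config$fs))
  trials <- list()
  k <- 0L
  for (i in seq_len(n)) {
    for (side in c("more_affected", "less_affected")) {
      key <- paste(subjects$sex[i],
                   if (side == "more_affected") "more" else "less", sep = "_")
      cfg <- config
      cfg$pic_amplitude <- config$pic_amplitude * pic_scale[[key]]
      cfg$gain_range <- config$gain_range * gain_scale[[key]]
      for (proto in names(profiles)) {
        k <- k + 1L
        tr <- simulate_trial(cfg, profiles[[proto]], seed = trial_seeds[k],
                             subject_id = subjects$subject_id[i], side = side)
        tr$sex <- subjects$sex[i]
        trials[[k]] <- tr
      }
    }
  }
  structure(list(subjects = subjects, trials = trials, seed = as.integer(seed)),
            class = "mu_cohort")
}

#' @export
print.mu_cohort <- function(x, ...) {
  cat(sprintf("<mu_cohort> %d subjects (%d trials), seed %d\n",
              nrow(x$subjects), length(x$trials), x$seed))
  invisible(x)
}
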