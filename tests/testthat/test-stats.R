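test_that("pooled t test reproduces the cohort weight comparison and
           degenerate cases", {
  w <- pooled_t_test(mean1 = 57.6, sd1 = 9.0, n1 = 14,
                     mean2 = 62.2, sd2 = 5.2, n2 = 13)
  expect_equal(round(w$p_value, 3), 0.120)
  expect_equal(w$df, 25)
  same <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$estimate, 0)
  const_eq <- pooled_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(const_eq$p_value, 1)
  expect_error(pooled_t_test(c(2, 2, 2), c(3, 3)), "degenerate")
})

test_that("raw-sample and summary-statistic t paths agree with each other
           and with the stats oracle", {
  set.seed(31)
  for (k in 1:10) {
    x <- rnorm(sample(4:20, 1), 10, 2)
    y <- rnorm(sample(4:20, 1), 11, 3)
    raw <- pooled_t_test(x, y)
    summ <- pooled_t_test(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                          mean2 = mean(y), sd2 = sd(y), n2 = length(y))
    expect_equal(raw$p_value, summ$p_value, tolerance = 1e-12)
    expect_equal(raw$ci95, summ$ci95, tolerance = 1e-12)
    oracle <- t.test(x, y, var.equal = TRUE)
    expect_equal(raw$p_value, oracle$p.value, tolerance = 1e-10)
    expect_equal(raw$ci95, as.numeric(oracle$conf.int), tolerance = 1e-10)
  }
})

test_that("pooled t p value is consistent with a permutation test", {
  set.seed(8)
  x <- rnorm(10, 0, 1); y <- rnorm(10, 0.8, 1)
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  perm <- replicate(10000, {
    idx <- sample(20, 10)
    abs(mean(pool[idx]) - mean(pool[-idx]))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  p_t <- pooled_t_test(x, y)$p_value
  expect_lt(abs(p_t - p_perm), 0.03)
})

test_that("chi-square reproduces the medication-usage comparisons", {
  ldopa <- matrix(c(12, 12, 2, 1), nrow = 2)   # 12/14 vs 12/13 users
  res <- chi_square_2x2(ldopa)
  expect_equal(round(res$p_value, 3), 0.586)
  expect_equal(res$df, 1)
  agonist <- matrix(c(4, 3, 10, 10), nrow = 2) # 4/14 vs 3/13 users
  expect_equal(round(chi_square_2x2(agonist)$p_value, 3), 0.745)
  prop <- matrix(c(10, 20, 5, 10), nrow = 2)   # perfectly proportional
  res_p <- chi_square_2x2(prop)
  expect_equal(res_p$estimate, 0)
  expect_equal(res_p$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), nrow = 2)), "margin")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), nrow = 2)))
})

test_that("chi-square equals the brute-force statistic on random tables", {
  set.seed(17)
  for (k in 1:30) {
    tab <- matrix(rpois(4, 12) + 1, nrow = 2)
    res <- chi_square_2x2(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    brute <- sum((tab - expected)^2 / expected)
    expect_equal(res$estimate, brute, tolerance = 1e-10)
    expect_equal(res$p_value, pchisq(brute, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- seq(1, 10)
  expect_equal(pearson_r(x, 2 * x)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  expect_error(pearson_r(x, rep(3, 10)), "variance")
  expect_error(pearson_r(c(1, 2), c(3, 4)), "3 complete")
  set.seed(41)
  hits <- mean(replicate(200, pearson_r(rnorm(30), rnorm(30))$p_value < 0.05))
  expect_gt(hits, 0.005); expect_lt(hits, 0.12)
})

test_that("LOESS equals the line on linear data and a WLS oracle at a
           point", {
  set.seed(51)
  x <- sort(runif(40, 0, 10)); y <- 2 + 0.7 * x
  fit <- loess_fit(x, y)
  expect_equal(fit$fitted, 2 + 0.7 * fit$x, tolerance = 1e-8)
  # independent oracle: closed-form weighted least squares with tricube
  # weights at one evaluation point (non-robust pass)
  wls_oracle <- function(x, y, x0, span) {
    n <- length(x); q <- ceiling(span * n)
    d <- abs(x - x0); h <- sort(d)[q]
    w <- (1 - pmin(d / h, 1)^3)^3
    sw <- sum(w); sx <- sum(w * (x - x0)); sxx <- sum(w * (x - x0)^2)
    sy <- sum(w * y); sxy <- sum(w * (x - x0) * y)
    (sxx * sy - sx * sxy) / (sw * sxx - sx^2)
  }
  yy <- y + sin(x)
  fit2 <- loess_fit(x, yy, iterations = 0)
  for (i in c(5, 20, 35)) {
    expect_equal(fit2$fitted[i], wls_oracle(x, yy, fit2$x[i], 0.75),
                 tolerance = 1e-9)
  }
  expect_error(loess_fit(x[1:9], y[1:9]), "10 points")
  expect_error(loess_fit(x, y, span = 0.01), "span")
})

test_that("robust LOESS shrugs off a gross outlier", {
  set.seed(52)
  x <- sort(runif(50, 0, 10)); y <- 1 + x
  k <- 25; y_out <- y; y_out[k] <- y[k] + 30
  robust <- loess_fit(x, y_out, iterations = 2)
  naive <- loess_fit(x, y_out, iterations = 0)
  resid_out <- 30
  dev_robust <- abs(robust$fitted[k] - (1 + x[k]))
  dev_naive <- abs(naive$fitted[k] - (1 + x[k]))
  expect_lt(dev_robust, 0.1 * resid_out)
  expect_gt(dev_naive, dev_robust)
})

test_that("subject-side aggregation and laterality indices", {
  met <- data.frame(subject_id = rep("S01", 4),
                    sex = "female",
                    side = rep(c("more_affected", "less_affected"), each = 2),
                    protocol = "ramp_hold",
                    unit_id = c("A", "B", "C", "D"),
                    mean_dr_pps = c(10, 12, 9, 11),
                    cv_isi_pct = c(14, 16, 12, 14),
                    rt_pct_mvc = c(5, 10, 6, 11))
  dfu <- data.frame(subject_id = "S01",
                    side = c("more_affected", "less_affected"),
                    delta_f_pps = c(0.9, 3.9))
  agg <- aggregate_subject_side(met, dfu)
  more <- agg[agg$side == "more_affected", ]
  expect_equal(more$mean_dr_pps, 11)
  expect_equal(more$n_units, 2L)
  lat <- laterality(agg)
  expect_equal(lat$delta_dr_pps, 11 - 10)
  expect_equal(lat$delta_cv_pct, 15 - 13)
  expect_equal(lat$delta_delta_f_pps, 3.9 - 0.9)
  # single-unit side keeps its own values; missing side is skipped
  single <- aggregate_subject_side(met[c(1, 3), ], dfu)
  expect_equal(single$mean_dr_pps[single$side == "more_affected"], 10)
  expect_equal(single$mean_dr_pps[single$side == "less_affected"], 9)
  one_side <- laterality(agg[agg$side == "more_affected", ])
  expect_null(one_side)
})

test_that("laterality deltas follow the documented orientation", {
  summaries <- data.frame(subject_id = c("S01", "S01"),
                          sex = "male",
                          side = c("more_affected", "less_affected"),
                          mean_dr_pps = c(11.7, 10.2),
                          cv_isi_pct = c(15, 15),
                          delta_f_pps = c(2, 2))
  lat <- laterality(summaries)
  expect_equal(lat$delta_dr_pps, 1.5)
  expect_equal(lat$delta_cv_pct, 0)
  expect_equal(lat$delta_delta_f_pps, 0)
})

test_that("mixed model marginal means equal cell means on balanced data
           and levels of analysis agree when units are identical", {
  d <- expand.grid(subject_id = sprintf("S%02d", 1:8),
                   side = c("more_affected", "less_affected"),
                   stringsAsFactors = FALSE)
  d$sex <- ifelse(as.integer(sub("S", "", d$subject_id)) <= 4,
                  "female", "male")
  set.seed(61)
  d$y <- 10 + (d$sex == "female") + 0.5 * (d$side == "more_affected") +
    rnorm(nrow(d), 0, 0.3)
  fit <- suppressMessages(fit_mixed_model(d, "y"))
  cells <- aggregate(y ~ sex + side, d, mean)
  merged <- merge(fit$emmeans, cells, by = c("sex", "side"))
  expect_equal(merged$emmean, merged$y, tolerance = 1e-6)
  # duplicating every row as "units" must not move the fixed effects
  d3 <- d[rep(seq_len(nrow(d)), each = 3), ]
  fit3 <- suppressMessages(fit_mixed_model(d3, "y"))
  expect_equal(lme4::fixef(fit$model), lme4::fixef(fit3$model),
               tolerance = 1e-6)
  expect_error(fit_mixed_model(d[d$sex == "female", ], "y"), "both")
})

test_that("onion-skin check recovers constructed associations", {
  # perfect construction: mean_dr = 20 - 0.3 RT
  met <- data.frame(sex = "female", side = "more_affected",
                    rt_pct_mvc = seq(2, 20, length.out = 12))
  met$mean_dr_pps <- 20 - 0.3 * met$rt_pct_mvc
  res <- onion_skin_check(met)
  expect_equal(res$r, -1, tolerance = 1e-12)
  curves <- attr(res, "loess")
  expect_length(curves, 1L)
  # simulated pools with the onion-skin ceiling: negative per stratum
  cfg <- sim_config(fs = 256)
  prof <- generate_protocol("ramp_hold", 30, fs = 256)
  trial <- simulate_trial(cfg, prof, seed = 3)
  tq <- lowpass_torque(trial$torque)
  met_sim <- unit_metrics(qc_spiketrains(trial$spikes)$units, tq,
                          sex = "female")
  res_sim <- onion_skin_check(met_sim)
  expect_lt(res_sim$r, -0.2)
})

test_that("a small calibration run of the mixed model is sane", {
  r <- calibrate_mixed_model(n_rep = 8, seed = 99)
  expect_lte(r$type1_rate, 0.5)
  expect_gte(r$coverage, 0.5)
  expect_equal(r$n_rep, 8)
})
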