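test_that("SVR smoothing reproduces a constant rate within epsilon", {
  tr <- spike_train(seq(0, 5, by = 0.1))
  sm <- smooth_idr_svr(compute_idr(tr))
  expect_true(all(abs(sm$rate - 10) <= 0.2 + 1e-6))
  expect_equal(sm$span, c(0.1, 5))
  short <- compute_idr(spike_train(seq(0, 0.5, by = 0.1)))
  expect_error(smooth_idr_svr(short), "10 IDR")
})

test_that("SVR tracks a noiseless triangle rate profile closely", {
  cfg <- small_config()
  prof <- generate_protocol("triangle", 30, fs = 256)
  trial <- simulate_trial(cfg, prof, seed = 1)
  u <- trial$truth$units[1, ]
  sm <- smooth_idr_svr(compute_idr(trial$spikes[[1]]))
  truth <- analytic_rate(sm$time, u, prof)
  rms <- sqrt(mean((sm$rate - truth)^2))
  expect_lt(rms, 0.25)
})

test_that("epsilon-insensitive loss resists a single outlier", {
  set.seed(5)
  times <- seq(0.1, 5, by = 0.1)
  rates <- 10 + 0.5 * times
  out_idx <- 25
  mk_idr <- function(r) {
    structure(data.frame(time = times, rate = r,
                         segment = 1L),
              class = c("idr_series", "data.frame"))
  }
  dirty <- rates; dirty[out_idx] <- dirty[out_idx] + 5
  sm_clean <- smooth_idr_svr(mk_idr(rates))
  sm_dirty <- smooth_idr_svr(mk_idr(dirty))
  t_out <- times[out_idx]
  dev <- abs(smoothed_rate_at(sm_dirty, t_out) -
             smoothed_rate_at(sm_clean, t_out))
  # the linear epsilon-insensitive loss caps the outlier's pull at about
  # the tube width; a squared loss would be dragged a large fraction of
  # the full 5 pps residual
  expect_lt(dev, 0.3)
  expect_lt(dev, 0.1 * 5)
})

test_that("pair delta-F subtracts reporter rates at the test unit's
           transitions", {
  sm <- fake_smoothed(seq(0, 10, by = 0.1), rep(10, 101))
  expect_equal(pair_delta_f(sm, 2, 8), 0)
  ramp <- fake_smoothed(seq(0, 10, by = 0.1),
                        c(seq(5, 15, length.out = 51),
                          seq(14.8, 5, length.out = 50)))
  f_on <- smoothed_rate_at(ramp, 3); f_off <- smoothed_rate_at(ramp, 9)
  expect_equal(pair_delta_f(ramp, 3, 9), f_on - f_off)
  drop3 <- fake_smoothed(c(0, 5, 10), c(10, 10, 7))
  expect_equal(pair_delta_f(drop3, 5, 10), 3)
  expect_error(pair_delta_f(sm, -1, 8), "covered|span")
  expect_error(pair_delta_f(sm, 2, 11), "covered|span")
})

test_that("pair criteria reject short gaps, weak correlation, and flat
           reporters", {
  tq <- ramp_torque(fs = 256)
  # reporter recruited at t=1 with rising-falling rate, well modulated
  rep_rate <- function(t) 10 + 2 * sin(pi * t / 28)
  rep_tr <- spike_train(spikes_from_rate(rep_rate, 1, 29), unit_id = "R")
  # gap criterion: test recruited only 0.5 s after the reporter
  near_tr <- spike_train(spikes_from_rate(function(t) 9, 1.5, 27),
                         unit_id = "N")
  pairs <- enumerate_pairs(list(rep_tr, near_tr), tq)
  row <- pairs[pairs$reporter_id == "R" & pairs$test_id == "N", ]
  expect_false(row$accepted)
  expect_match(row$reject_reason, "recruit_gap")
  # correlation criterion: test rate anti-correlated with the reporter
  anti_tr <- spike_train(spikes_from_rate(function(t) 14 - 2 * sin(pi * t / 28),
                                          3, 27), unit_id = "A")
  pairs2 <- enumerate_pairs(list(rep_tr, anti_tr), tq)
  row2 <- pairs2[pairs2$reporter_id == "R" & pairs2$test_id == "A", ]
  expect_false(row2$accepted)
  expect_lt(row2$rate_rate_r, 0.7)
  expect_match(row2$reject_reason, "rate_rate_r")
  # modulation criterion: almost-flat reporter
  flat_tr <- spike_train(spikes_from_rate(function(t) 10 + 0.005 * t, 1, 29),
                         unit_id = "F")
  test_tr <- spike_train(spikes_from_rate(function(t) 10 + 0.005 * t, 3, 27),
                         unit_id = "T")
  pairs3 <- enumerate_pairs(list(flat_tr, test_tr), tq)
  row3 <- pairs3[pairs3$reporter_id == "F" & pairs3$test_id == "T", ]
  expect_lt(row3$reporter_range_pps, 0.5)
  expect_match(row3$reject_reason, "reporter_range")
})

test_that("inclusion thresholds are closed bounds", {
  tq <- ramp_torque(fs = 256)
  rate <- function(t) 10 + 0.2 * t
  rep_tr <- spike_train(spikes_from_rate(rate, 1, 29), unit_id = "R")
  # first spike of the test exactly 1.000 s after the reporter's
  test_times <- spikes_from_rate(rate, 2, 27)
  expect_equal(test_times[1] - 1, rep_tr$times[1])
  test_tr <- spike_train(test_times, unit_id = "T")
  pairs <- enumerate_pairs(list(rep_tr, test_tr), tq)
  row <- pairs[pairs$test_id == "T", ]
  expect_equal(row$recruit_gap_s, 1.0)
  expect_true(row$accepted)
  # raising the gap threshold infinitesimally flips the decision
  stricter <- enumerate_pairs(list(rep_tr, test_tr), tq,
                              min_gap_s = 1.0 + 1e-9)
  expect_false(stricter[stricter$test_id == "T", ]$accepted)
})

test_that("delta-F never exceeds the reporter's modulation range", {
  cfg <- deltaf_validation_config()
  cfg$fs <- 256
  prof <- generate_protocol("triangle", 30, fs = 256)
  for (s in 1:3) {
    trial <- simulate_trial(cfg, prof, seed = s)
    tq <- lowpass_torque(trial$torque)
    qc <- qc_spiketrains(trial$spikes)
    pairs <- enumerate_pairs(qc$units, tq)
    ok <- !is.na(pairs$delta_f_pps)
    expect_true(all(abs(pairs$delta_f_pps[ok]) <=
                      pairs$reporter_range_pps[ok] + 1e-9))
    acc <- pairs[pairs$accepted, ]
    expect_true(all(acc$recruit_gap_s >= 1.0))
    expect_true(all(acc$rate_rate_r >= 0.7))
    expect_true(all(acc$reporter_range_pps >= 0.5))
  }
})

test_that("estimated delta-F increases strictly with the injected PIC", {
  prof <- generate_protocol("triangle", 30, fs = 256)
  est <- vapply(c(2, 4, 6), function(p) {
    cfg <- sim_config(n_units = 2, rt_range = c(4, 10),
                      gain_range = c(0.5, 0.5), pic_amplitude = c(1, p),
                      isi_cv = 0, fs = 256, torque_noise_sd = 0)
    trial <- simulate_trial(cfg, prof, seed = 1)
    tq <- lowpass_torque(trial$torque)
    pairs <- enumerate_pairs(trial$spikes, tq)
    pairs$delta_f_pps[1]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_equal(est, c(1, 2, 3), tolerance = 0.4)
})

test_that("unit-wise delta-F averages accepted reporters only", {
  pairs <- data.frame(reporter_id = c("A", "B", "C", "A"),
                      test_id = c("X", "X", "X", "Y"),
                      delta_f_pps = c(2, 3, 99, 4),
                      accepted = c(TRUE, TRUE, FALSE, TRUE))
  uw <- unitwise_delta_f(pairs)
  expect_equal(uw$delta_f_pps[uw$test_id == "X"], 2.5)
  expect_equal(uw$n_reporters[uw$test_id == "X"], 2L)
  expect_equal(uw$delta_f_pps[uw$test_id == "Y"], 4)
  none <- unitwise_delta_f(pairs[pairs$reporter_id == "C", ])
  expect_equal(nrow(none), 0L)
})
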