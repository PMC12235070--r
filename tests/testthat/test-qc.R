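mk_train <- function(times, pnr = 40, protocol = "triangle", ...)
  spike_train(times, pnr_db = pnr, protocol = protocol, ...)

test_that("PNR gate removes only trains strictly below threshold", {
  trains <- list(mk_train(c(1, 1.1, 1.2), pnr = 29.9, unit_id = "A"),
                 mk_train(c(1, 1.1, 1.2), pnr = 30.0, unit_id = "B"),
                 mk_train(c(1, 1.1, 1.2), pnr = 41.2, unit_id = "C"))
  res <- filter_pnr(trains)
  expect_identical(vapply(res$units, function(u) u$unit_id, character(1)),
                   c("B", "C"))
  expect_identical(res$report$pass_pnr, c(FALSE, TRUE, TRUE))
  # all above threshold: identity
  ok <- filter_pnr(trains[2:3])
  expect_length(ok$units, 2L)
  # empty input
  expect_length(filter_pnr(list())$units, 0L)
  # missing PNR: retained but flagged
  na_tr <- mk_train(c(1, 1.1), pnr = NA)
  res_na <- filter_pnr(list(na_tr))
  expect_length(res_na$units, 1L)
  expect_true(res_na$report$pnr_missing)
})

test_that("ISI bounds drop double-picks and segment long pauses", {
  # short ISI: later spike removed, surviving 120 ms ISI kept
  r1 <- remove_isi_outliers(mk_train(c(0, 0.020, 0.120)))
  expect_equal(r1$n_spikes_removed, 1L)
  expect_equal(r1$train$times, c(0, 0.120))
  expect_equal(r1$n_isi_excluded, 0L)
  # all ISIs at 100 ms: untouched
  r2 <- remove_isi_outliers(mk_train(seq(0, 1, by = 0.1)))
  expect_equal(r2$n_spikes_removed, 0L)
  expect_equal(r2$n_isi_excluded, 0L)
  # 300 ms pause: spikes kept, interval excluded, segments split
  r3 <- remove_isi_outliers(mk_train(c(0, 0.3)))
  expect_equal(r3$n_spikes_removed, 0L)
  expect_equal(r3$n_isi_excluded, 1L)
  expect_equal(r3$train$segment, c(1L, 2L))
  # ISIs just inside the physiological band are retained
  r4 <- remove_isi_outliers(mk_train(c(0, 0.034, 0.284)))
  expect_equal(r4$n_spikes_removed, 0L)
  expect_equal(r4$n_isi_excluded, 0L)
  # boundary semantics are closed: an ISI equal to the bound survives
  isi_ms <- diff(c(0, 0.05)) * 1000
  r5 <- remove_isi_outliers(mk_train(c(0, 0.05)), low_ms = isi_ms,
                            high_ms = 250)
  expect_equal(r5$n_spikes_removed, 0L)
  r6 <- remove_isi_outliers(mk_train(c(0, 0.2)), low_ms = 33.3,
                            high_ms = diff(c(0, 0.2)) * 1000)
  expect_equal(r6$n_isi_excluded, 0L)
})

test_that("the reference toy train loses exactly 1 spike and 1 ISI", {
  toy <- c(0, 0.020, 0.120, 0.420)
  # brute-force oracle: enumerate ISIs after each deletion step
  brute <- function(times, low = 0.0333, high = 0.250) {
    removed <- 0L
    repeat {
      isi <- diff(times)
      short <- which(isi < low)
      if (!length(short)) break
      times <- times[-(short[1] + 1)]
      removed <- removed + 1L
    }
    isi <- diff(times)
    list(removed = removed, excluded = sum(isi > high),
         surviving = sum(isi >= low & isi <= high))
  }
  oracle <- brute(toy)
  res <- remove_isi_outliers(mk_train(toy))
  expect_equal(res$n_spikes_removed, oracle$removed)
  expect_equal(res$n_spikes_removed, 1L)
  expect_equal(res$n_isi_excluded, oracle$excluded)
  expect_equal(res$n_isi_excluded, 1L)
  # exactly one ISI survives for rate statistics
  idr <- compute_idr(res$train)
  expect_equal(nrow(idr), oracle$surviving)
  expect_equal(nrow(idr), 1L)
})

test_that("discharge-rate CV exclusion keeps the boundary and flags
           unscorable units", {
  # rates {7, 13, 10} pps: mean 10, sample SD 3 -> CV 30%
  t30 <- mk_train(cumsum(c(0.5, 1 / 7, 1 / 13, 1 / 10)))
  cv <- cv_of_dr(t30)
  expect_equal(cv, 30, tolerance = 1e-9)
  keep <- exclude_high_cv_units(list(t30), max_cv_pct = cv)
  expect_length(keep$units, 1L)          # boundary value retained
  drop <- exclude_high_cv_units(list(t30), max_cv_pct = cv - 1e-6)
  expect_length(drop$units, 0L)
  # constant-rate unit always kept
  const <- mk_train(seq(1, 3, by = 0.1))
  expect_length(exclude_high_cv_units(list(const))$units, 1L)
  # two spikes: flagged, not scored
  two <- mk_train(c(1, 1.1))
  res2 <- exclude_high_cv_units(list(two))
  expect_length(res2$units, 0L)
  expect_false(res2$report$scored)
})

test_that("QC filters are idempotent and order-insensitive across criteria", {
  set.seed(3)
  trains <- lapply(1:6, function(k) {
    times <- sort(runif(40, 0, 20))
    times <- times[c(TRUE, diff(times) > 0.04)]
    mk_train(times, pnr = sample(c(25, 35, 45), 1),
             unit_id = sprintf("U%d", k))
  })
  once <- filter_pnr(trains)
  twice <- filter_pnr(once$units)
  expect_identical(vapply(twice$units, function(u) u$unit_id, character(1)),
                   vapply(once$units, function(u) u$unit_id, character(1)))
  for (tr in trains) {
    a <- remove_isi_outliers(tr)
    b <- remove_isi_outliers(a$train)
    expect_identical(b$train$times, a$train$times)
    expect_equal(b$n_spikes_removed, 0L)
  }
  # PNR and ISI rules act on disjoint information: same survivors either way
  ab <- lapply(filter_pnr(trains)$units,
               function(u) remove_isi_outliers(u)$train)
  ba <- filter_pnr(lapply(trains,
                          function(u) remove_isi_outliers(u)$train))$units
  expect_identical(lapply(ab, `[[`, "times"), lapply(ba, `[[`, "times"))
})

test_that("clean simulator output passes QC at a high rate and injected
           artifacts are caught", {
  cfg <- deltaf_validation_config()
  cfg$fs <- 256
  prof <- generate_protocol("triangle", 30, fs = 256)
  pass <- total <- 0
  for (s in 1:3) {
    trial <- simulate_trial(cfg, prof, seed = s)
    qc <- qc_spiketrains(trial$spikes)
    pass <- pass + qc$n_units_out; total <- total + qc$n_units_in
  }
  expect_gte(pass / total, 0.95)
  # artifact injection: the doublet's 20 ms ISI is deleted, the 300 ms
  # pause splits a segment
  cfg_bad <- cfg; cfg_bad$inject_artifacts <- TRUE
  trial <- simulate_trial(cfg_bad, prof, seed = 4)
  cleaned <- lapply(trial$spikes, remove_isi_outliers)
  expect_gte(sum(vapply(cleaned, `[[`, integer(1), "n_spikes_removed")), 1L)
  expect_gte(sum(vapply(cleaned, `[[`, integer(1), "n_isi_excluded")), 1L)
})
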