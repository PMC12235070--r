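#' Gate spike trains on pulse-to-noise ratio
#'
#' Decomposed trains with a pulse-to-noise ratio (PNR) below the threshold
#' indicate an identification accuracy below roughly 90% and are removed.
#' The boundary value itself is kept (only values strictly below the
#' threshold are eliminated). Trains lacking PNR metadata are retained but
#' flagged in the report.
#'
#' @param units A list of [spike_train()] objects.
#' @param threshold_db PNR threshold in dB (default 30).
#' @return A list with `units` (surviving trains) and `report`, a data frame
#'   with one row per input unit: `unit_id`, `pnr_db`, `pnr_missing`,
#'   `pass_pnr`.
#' @export
filter_pnr <- function(units, threshold_db = 30) {
  stopifnot(is.finite(threshold_db))
  if (inherits(units, "spike_train")) units <- list(units)
  if (!length(units))
    return(list(units = list(),
                report = data.frame(unit_id = character(),
                                    pnr_db = numeric(),
                                    pnr_missing = logical(),
                                    pass_pnr = logical())))
  pnr <- vapply(units, function(u) u$pnr_db, numeric(1))
  missing <- is.na(pnr)
  pass <- missing | pnr >= threshold_db
  report <- data.frame(
    unit_id = vapply(units, function(u) u$unit_id, character(1)),
    pnr_db = pnr, pnr_missing = missing, pass_pnr = pass,
    stringsAsFactors = FALSE)
  list(units = units[pass], report = report)
}

#' Delete non-physiological interspike intervals from one train
#'
#' Interspike intervals (ISIs) below `low_ms` or above `high_ms`
#' (corresponding to 30 Hz and 4 Hz at the defaults) are treated as
#' decomposition artifacts rather than physiological discharge. The two
#' cases are handled differently:
#'
#' * short ISI (< `low_ms`): the later spike of the offending pair is
#'   removed (a decomposition double-pick), and intervals are re-evaluated
#'   after each removal;
#' * long ISI (> `high_ms`): both spikes are kept, but the gap becomes a
#'   segment boundary — no instantaneous rate is computed across it and it
#'   is excluded from ISI statistics.
#'
#' Boundary values (exactly `low_ms` or `high_ms`) are retained.
#'
#' @param train A [spike_train()].
#' @param low_ms,high_ms ISI bounds in milliseconds (defaults 33.3 and 250).
#' @return A list with `train` (the cleaned train, segment ids set),
#'   `n_spikes_removed` and `n_isi_excluded` (long-pause intervals).
#' @export
remove_isi_outliers <- function(train, low_ms = 33.3, high_ms = 250) {
  stopifnot(inherits(train, "spike_train"), low_ms > 0, high_ms > low_ms)
  times <- train$times
  removed <- 0L
  # iteratively drop the later spike of each short ISI
  repeat {
    if (length(times) < 2L) break
    isi_ms <- diff(times) * 1000
    bad <- which(isi_ms < low_ms)
    if (!length(bad)) break
    times <- times[-(bad[1] + 1L)]
    removed <- removed + 1L
  }
  if (length(times) >= 2L) {
    isi_ms <- diff(times) * 1000
    long <- isi_ms > high_ms
    segment <- c(1L, 1L + cumsum(long))
    n_long <- sum(long)
  } else {
    segment <- rep(1L, length(times))
    n_long <- 0L
  }
  out <- spike_train(times, unit_id = train$unit_id,
                     subject_id = train$subject_id, side = train$side,
                     protocol = train$protocol, pnr_db = train$pnr_db,
                     segment = segment)
  list(train = out, n_spikes_removed = removed, n_isi_excluded = n_long)
}

#' Exclude units with excessive discharge-rate variability
#'
#' Units whose coefficient of variation of the discharge rate, computed over
#' the analysis window, exceeds `max_cv_pct` are removed; the boundary value
#' is retained (only values strictly above the threshold are excluded).
#' Units with fewer than 3 instantaneous-rate values in the window cannot be
#' scored and are flagged unusable (removed, with `scored = FALSE`).
#'
#' The analysis window defaults to the 15-s plateau of the ramp-hold task
#' (15-30 s on the protocol clock); for triangle trials the unit's full
#' active span is used.
#'
#' @param units A list of QC'd [spike_train()] objects (run
#'   [remove_isi_outliers()] first so segment boundaries are respected).
#' @param max_cv_pct CV threshold in percent (default 30).
#' @param window Length-2 numeric analysis window in seconds, or `NULL` for
#'   the protocol default described above.
#' @return A list with `units` (surviving trains) and `report`: one row per
#'   input unit with `unit_id`, `cv_dr_pct`, `scored`, `pass_cv`.
#' @export
exclude_high_cv_units <- function(units, max_cv_pct = 30, window = NULL) {
  if (inherits(units, "spike_train")) units <- list(units)
  stopifnot(max_cv_pct >= 0)
  score_one <- function(u) {
    win <- window
    if (is.null(win)) {
      win <- if (u$protocol == "ramp_hold") c(15, 30) else
        if (length(u$times)) range(u$times) else c(0, 0)
    }
    idr <- tryCatch(compute_idr(u), error = function(e) NULL)
    if (is.null(idr)) return(c(cv = NA_real_, scored = 0))
    sel <- idr$time >= win[1] & idr$time <= win[2]
    rates <- idr$rate[sel]
    if (length(rates) < 3L) return(c(cv = NA_real_, scored = 0))
    c(cv = 100 * stats::sd(rates) / mean(rates), scored = 1)
  }
  if (!length(units))
    return(list(units = list(),
                report = data.frame(unit_id = character(),
                                    cv_dr_pct = numeric(),
                                    scored = logical(),
                                    pass_cv = logical())))
  sc <- t(vapply(units, score_one, numeric(2)))
  scored <- sc[, "scored"] == 1
  pass <- scored & sc[, "cv"] <= max_cv_pct
  report <- data.frame(
    unit_id = vapply(units, function(u) u$unit_id, character(1)),
    cv_dr_pct = sc[, "cv"], scored = scored, pass_cv = pass,
    stringsAsFactors = FALSE)
  list(units = units[pass], report = report)
}

#' Full spike-train quality control
#'
#' Applies the three exclusion rules in fixed order — PNR gate, ISI bounds,
#' discharge-rate CV — and assembles a per-unit report. Each rule is
#' idempotent, and the PNR and ISI rules act on disjoint criteria, so the
#' surviving set does not depend on their relative order.
#'
#' @param units A list of [spike_train()] objects (one trial).
#' @param pnr_db PNR threshold, dB.
#' @param isi_low_ms,isi_high_ms ISI bounds, ms.
#' @param max_cv_pct Discharge-rate CV threshold, percent.
#' @param cv_window Analysis window for the CV rule (see
#'   [exclude_high_cv_units()]).
#' @return A list of class `qc_result`: `units` (surviving, ISI-cleaned
#'   trains), `report` (per input unit: PNR, spikes removed, ISIs excluded,
#'   CV, pass flags per rule and overall), `n_units_in`, `n_units_out`.
#' @export
qc_spiketrains <- function(units, pnr_db = 30, isi_low_ms = 33.3,
                           isi_high_ms = 250, max_cv_pct = 30,
                           cv_window = NULL) {
  if (inherits(units, "spike_train")) units <- list(units)
  n_in <- length(units)
  ids <- vapply(units, function(u) u$unit_id, character(1))
  p <- filter_pnr(units, threshold_db = pnr_db)
  cleaned <- lapply(p$units, remove_isi_outliers,
                    low_ms = isi_low_ms, high_ms = isi_high_ms)
  trains <- lapply(cleaned, `[[`, "train")
  isi_rep <- data.frame(
    unit_id = vapply(trains, function(u) u$unit_id, character(1)),
    n_spikes_removed = vapply(cleaned, `[[`, integer(1), "n_spikes_removed"),
    n_isi_excluded = vapply(cleaned, `[[`, integer(1), "n_isi_excluded"),
    stringsAsFactors = FALSE)
  cv <- exclude_high_cv_units(trains, max_cv_pct = max_cv_pct,
                              window = cv_window)
  report <- p$report
  report <- merge(report, isi_rep, by = "unit_id", all.x = TRUE, sort = FALSE)
  report <- merge(report, cv$report, by = "unit_id", all.x = TRUE,
                  sort = FALSE)
  report$pass <- report$pass_pnr & !is.na(report$pass_cv) & report$pass_cv
  report <- report[match(ids, report$unit_id), , drop = FALSE]
  rownames(report) <- NULL
  structure(list(units = cv$units, report = report,
                 n_units_in = n_in, n_units_out = length(cv$units)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d/%d units pass QC\n",
              x$n_units_out, x$n_units_in))
  invisible(x)
}
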