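#' Run the full analysis pipeline
#'
#' Orchestrates the per-trial stages — torque conditioning, spike-train QC,
#' discharge metrics, and (triangle trials only) the paired-unit delta-F
#' analysis — followed by the group layer: subject-side aggregation,
#' laterality indices with between-sex pooled t tests, two-way mixed-effects
#' models (sex, side, their interaction, random subject intercept; the
#' recruitment threshold as covariate for the discharge-rate outcome),
#' Pearson correlations with UPDRS Part III per sex-by-side stratum, and the
#' onion-skin check. A failing trial is isolated and logged; the run
#' continues with the remaining trials.
#'
#' @param x Either a manifest data frame from [read_manifest()] (file-based
#'   run) or a [simulate_cohort()] object (in-memory run).
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, every table plus a
#'   machine-readable provenance record is written there as delimited
#'   text/JSON.
#' @param model_level `"subject"` (default) fits the mixed models on
#'   subject-side aggregates; `"unit"` fits them on unit-level rows.
#' @return A list of class `mu_results` with elements `metrics` (unit
#'   metrics table), `qc` (per-unit QC report), `deltaf_pairs`,
#'   `deltaf_units`, `subject_side`, `laterality`, `stats` (list:
#'   `laterality_tests`, `mixed_models`, `updrs_correlations`,
#'   `onion_skin`), `trial_log` and `provenance`.
#' @export
run_pipeline <- function(x, config = run_config(), out_dir = NULL,
                         model_level = c("subject", "unit")) {
  model_level <- match.arg(model_level)
  stopifnot(inherits(config, "run_config"))
  trials <- as_trial_list(x)
  metrics <- list(); qc_rows <- list(); pair_rows <- list()
  unit_rows <- list(); log_rows <- list()
  for (tr in trials) {
    status <- "ok"; msg <- ""
    res <- tryCatch(process_trial(load_trial(tr), config),
                    error = function(e) {
      status <<- "failed"; msg <<- conditionMessage(e); NULL
    })
    if (!is.null(res)) {
      metrics[[length(metrics) + 1L]] <- res$metrics
      qc_rows[[length(qc_rows) + 1L]] <- res$qc
      if (!is.null(res$pairs) && nrow(res$pairs))
        pair_rows[[length(pair_rows) + 1L]] <- res$pairs
      if (!is.null(res$units) && nrow(res$units))
        unit_rows[[length(unit_rows) + 1L]] <- res$units
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      subject_id = tr$subject_id, side = tr$side, protocol = tr$protocol,
      status = status, message = msg, stringsAsFactors = FALSE)
  }
  metrics <- rbind_rows(metrics)
  qc <- rbind_rows(qc_rows)
  pairs <- if (length(pair_rows))
    rbind_rows(pair_rows) else NULL
  uw <- if (length(unit_rows))
    rbind_rows(unit_rows) else NULL
  subjects <- attr(trials, "subjects")
  if (is.null(metrics) || !nrow(metrics)) {
    summaries <- NULL; lat <- NULL
  } else {
    summaries <- aggregate_subject_side(metrics, uw, subjects = subjects)
    lat <- laterality(summaries)
  }
  stats <- group_statistics(metrics, summaries, lat, model_level)
  prov <- list(config = unclass(config), seed = config$seed,
               package_version = as.character(utils::packageVersion("mudeltaf")),
               r_version = R.version.string,
               n_trials = length(trials),
               n_trials_ok = sum(vapply(log_rows, function(r)
                 r$status == "ok", logical(1))),
               n_units_in = if (!is.null(qc)) nrow(qc) else 0L,
               n_units_out = if (!is.null(qc)) sum(qc$pass) else 0L)
  out <- structure(
    list(metrics = metrics, qc = qc, deltaf_pairs = pairs,
         deltaf_units = uw, subject_side = summaries, laterality = lat,
         stats = stats,
         trial_log = rbind_rows(log_rows),
         provenance = prov),
    class = "mu_results")
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

# normalize the two input forms to a list of per-trial working objects
as_trial_list <- function(x) {
  if (inherits(x, "mu_cohort")) {
    trials <- lapply(x$trials, function(tr) {
      list(subject_id = tr$subject_id, sex = tr$sex, side = tr$side,
           protocol = tr$profile$kind, spikes = tr$spikes,
           torque = tr$torque, mvc_nm = NA_real_)
    })
    attr(trials, "subjects") <- x$subjects
    return(trials)
  }
  stopifnot(is.data.frame(x))
  trials <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    # files are read lazily inside the per-trial error boundary
    list(subject_id = row$subject_id, sex = row$sex, side = row$side,
         protocol = row$protocol, spike_path = row$spike_path,
         torque_path = row$torque_path, mvc_nm = row$mvc_nm)
  })
  cols <- intersect(c("subject_id", "sex", "mvc_nm", "updrs_iii"), names(x))
  attr(trials, "subjects") <- unique(x[cols])
  trials
}

load_trial <- function(tr) {
  if (is.null(tr[["spikes"]]))
    tr$spikes <- read_spike_trains(tr[["spike_path"]])
  if (is.null(tr[["torque"]]))
    tr$torque <- read_torque(tr[["torque_path"]])
  tr
}

process_trial <- function(tr, config) {
  torque <- lowpass_torque(tr$torque)
  if (torque$unit == "nm") torque <- normalize_torque(torque, tr$mvc_nm)
  qc <- qc_spiketrains(tr$spikes, pnr_db = config$pnr_db,
                       isi_low_ms = config$isi_low_ms,
                       isi_high_ms = config$isi_high_ms,
                       max_cv_pct = config$max_cv_pct)
  met <- unit_metrics(qc$units, torque, sex = tr$sex,
                      hold_window = config$hold_window)
  qc_rep <- cbind(subject_id = tr$subject_id, side = tr$side,
                  protocol = tr$protocol, qc$report,
                  stringsAsFactors = FALSE)
  pairs <- NULL; units <- NULL
  if (tr$protocol == "triangle" && length(qc$units) >= 2L) {
    dfres <- deltaf_trial(qc$units, torque, min_gap_s = config$gap_s,
                          min_r = config$min_r,
                          min_range_pps = config$min_range_pps,
                          grid_step_s = config$grid_step_s,
                          sigma_s = config$sigma_s,
                          epsilon = config$epsilon, cost = config$cost)
    pairs <- dfres$pairs
    attr(pairs, "smoothed") <- NULL
    if (nrow(pairs))
      pairs <- cbind(subject_id = tr$subject_id, side = tr$side,
                     as.data.frame(pairs), stringsAsFactors = FALSE)
    units <- dfres$units
  }
  list(metrics = met, qc = qc_rep, pairs = pairs, units = units)
}

group_statistics <- function(metrics, summaries, lat, model_level) {
  try_stat <- function(expr) tryCatch(expr, error = function(e) {
    message("group statistic skipped: ", conditionMessage(e)); NULL
  })
  lat_tests <- list()
  if (!is.null(lat) && "sex" %in% names(lat) &&
      length(unique(stats::na.omit(lat$sex))) == 2L) {
    for (v in c("delta_dr_pps", "delta_cv_pct", "delta_delta_f_pps")) {
      f <- lat[[v]][lat$sex == "female"]; m <- lat[[v]][lat$sex == "male"]
      f <- f[is.finite(f)]; m <- m[is.finite(m)]
      if (length(f) >= 2 && length(m) >= 2)
        lat_tests[[v]] <- try_stat(pooled_t_test(f, m))
    }
  }
  model_data <- if (model_level == "subject") summaries else metrics
  mixed <- list(
    cv_isi = try_stat(fit_mixed_model(model_data, "cv_isi_pct")),
    mean_dr = try_stat(fit_mixed_model(
      model_data, "mean_dr_pps",
      covariate = if ("rt_pct_mvc" %in% names(model_data)) "rt_pct_mvc")),
    delta_f = if ("delta_f_pps" %in% names(model_data))
      try_stat(fit_mixed_model(model_data, "delta_f_pps")) else NULL)
  updrs <- NULL
  if ("updrs_iii" %in% names(summaries) &&
      any(is.finite(summaries$updrs_iii))) {
    strata <- split(summaries, interaction(summaries$sex, summaries$side,
                                           drop = TRUE))
    rows <- lapply(strata, function(g) {
      res <- lapply(c(cv_isi_pct = "cv_isi_pct", mean_dr_pps = "mean_dr_pps",
                      delta_f_pps = "delta_f_pps"), function(v) {
        ok <- is.finite(g[[v]]) & is.finite(g$updrs_iii)
        if (sum(ok) >= 3) try_stat(pearson_r(g[[v]][ok], g$updrs_iii[ok]))
        else NULL
      })
      keep <- !vapply(res, is.null, logical(1))
      if (!any(keep)) return(NULL)
      data.frame(sex = g$sex[1], side = g$side[1],
                 metric = names(res)[keep],
                 r = vapply(res[keep], function(s) s$estimate, numeric(1)),
                 p_value = vapply(res[keep], function(s) s$p_value,
                                  numeric(1)),
                 stringsAsFactors = FALSE)
    })
    updrs <- rbind_rows(rows)
  }
  onion <- try_stat(onion_skin_check(
    metrics[metrics$protocol == "ramp_hold", , drop = FALSE]))
  list(laterality_tests = lat_tests, mixed_models = mixed,
       updrs_correlations = updrs, onion_skin = onion)
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && nrow(df))
      utils::write.csv(format_num_df(as.data.frame(df)),
                       file.path(out_dir, name), row.names = FALSE,
                       quote = FALSE)
  }
  wr(res$metrics, "unit_metrics.csv")
  wr(res$qc, "qc_report.csv")
  wr(res$deltaf_pairs, "deltaf_pairs.csv")
  wr(res$deltaf_units, "deltaf_units.csv")
  wr(res$subject_side, "subject_side.csv")
  wr(res$laterality, "laterality.csv")
  wr(res$trial_log, "trial_log.csv")
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mu_results <- function(x, ...) {
  cat(sprintf("<mu_results> %d/%d trials ok, %d/%d units pass QC\n",
              x$provenance$n_trials_ok, x$provenance$n_trials,
              x$provenance$n_units_out, x$provenance$n_units_in))
  invisible(x)
}
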