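#' Write and read spike trains as delimited text
#'
#' The canonical interchange format is comma-separated UTF-8 text with a
#' header row and one row per discharge: `subject_id`, `side`, `protocol`,
#' `unit_id`, `spike_time_s`, `pnr_db`. Times are seconds on the trial
#' clock (zero at recording start), full precision.
#'
#' @param trains A list of [spike_train()] objects (or one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  df <- spikes_to_table(trains)
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @return For `read_spike_trains`, a list of validated [spike_train()]
#'   objects.
#' @export
read_spike_trains <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  table_to_spikes(df)
}

#' Write and read a torque trace as two-column delimited text
#'
#' Columns are `time_s` and either `torque_nm` or `pct_mvc`, depending on
#' the trace unit; the sampling rate is recovered from the time column on
#' reading.
#'
#' @param trace A [torque_trace()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_torque <- function(trace, path) {
  stopifnot(inherits(trace, "torque_trace"))
  value_col <- if (trace$unit == "nm") "torque_nm" else "pct_mvc"
  df <- data.frame(time_s = torque_time(trace), value = trace$samples)
  names(df)[2] <- value_col
  utils::write.csv(format_num_df(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_torque
#' @return For `read_torque`, a [torque_trace()].
#' @export
read_torque <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("torque file lacks a time_s column")
  value_col <- intersect(c("torque_nm", "pct_mvc"), names(df))
  if (length(value_col) != 1L)
    stop("torque file must have exactly one of torque_nm / pct_mvc")
  dt <- diff(df$time_s)
  if (any(dt <= 0)) stop("torque time column must be strictly increasing")
  fs <- 1 / stats::median(dt)
  torque_trace(df[[value_col]], fs = fs,
               unit = if (value_col == "torque_nm") "nm" else "pct_mvc",
               t0 = df$time_s[1])
}

# full-precision numeric formatting for delimited output
format_num_df <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  df
}

#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline with its default. The
#' defaults are the analysis conventions used throughout: 30 dB PNR gate,
#' 33.3-250 ms ISI bounds, 30% discharge-rate CV exclusion, 1 s recruitment
#' gap, 0.7 rate-rate correlation, 0.5 pps reporter modulation, SVR
#' hyperparameters (2 s kernel width, 0.2 pps epsilon, cost 10) and a 10 ms
#' evaluation grid, with the ramp-hold plateau window at 15-30 s.
#'
#' @param pnr_db,isi_low_ms,isi_high_ms,max_cv_pct QC thresholds.
#' @param gap_s,min_r,min_range_pps Pair-inclusion thresholds.
#' @param sigma_s,epsilon,cost,grid_step_s SVR smoothing settings.
#' @param hold_window Ramp-hold plateau window, s.
#' @param seed Seed recorded in provenance.
#' @return A list of class `run_config`.
#' @export
run_config <- function(pnr_db = 30, isi_low_ms = 33.3, isi_high_ms = 250,
                       max_cv_pct = 30, gap_s = 1.0, min_r = 0.7,
                       min_range_pps = 0.5, sigma_s = 2, epsilon = 0.2,
                       cost = 10, grid_step_s = 0.01,
                       hold_window = c(15, 30), seed = 1L) {
  stopifnot(pnr_db > 0, isi_low_ms > 0, isi_high_ms > isi_low_ms,
            max_cv_pct >= 0, gap_s > 0, min_r > 0, min_range_pps > 0,
            sigma_s > 0, epsilon >= 0, cost > 0, grid_step_s > 0)
  structure(list(pnr_db = pnr_db, isi_low_ms = isi_low_ms,
                 isi_high_ms = isi_high_ms, max_cv_pct = max_cv_pct,
                 gap_s = gap_s, min_r = min_r,
                 min_range_pps = min_range_pps, sigma_s = sigma_s,
                 epsilon = epsilon, cost = cost, grid_step_s = grid_step_s,
                 hold_window = hold_window, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a trial manifest
#'
#' The manifest is a comma-separated table with one row per trial and the
#' required columns `subject_id`, `sex` (`female`/`male`), `side`
#' (`more_affected`/`less_affected`), `protocol` (`ramp_hold`/`triangle`),
#' `spike_path`, `torque_path`, `mvc_nm`; `updrs_iii` is optional. Paths
#' are resolved relative to the manifest's directory. Closed vocabularies
#' are enforced and duplicate (subject, side, protocol) keys rejected, with
#' the offending row number in the error message.
#'
#' @param path Manifest file path.
#' @param check_files Verify that referenced files exist (default `TRUE`).
#' @return A data frame of validated trial manifests with absolute paths.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "side", "protocol", "spike_path",
            "torque_path", "mvc_nm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  if (!"updrs_iii" %in% names(df)) df$updrs_iii <- NA_real_
  vocab <- list(sex = c("female", "male"),
                side = c("more_affected", "less_affected"),
                protocol = c("ramp_hold", "triangle"))
  for (col in names(vocab)) {
    bad <- which(!df[[col]] %in% vocab[[col]])
    if (length(bad))
      stop(sprintf("manifest row %d: %s token '%s' not in {%s}", bad[1], col,
                   df[[col]][bad[1]], paste(vocab[[col]], collapse = ", ")))
  }
  key <- paste(df$subject_id, df$side, df$protocol)
  if (anyDuplicated(key))
    stop(sprintf("manifest row %d: duplicate (subject, side, protocol) key",
                 which(duplicated(key))[1]))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  df$spike_path <- resolve(df$spike_path)
  df$torque_path <- resolve(df$torque_path)
  if (check_files) {
    for (col in c("spike_path", "torque_path")) {
      bad <- which(!file.exists(df[[col]]))
      if (length(bad))
        stop(sprintf("manifest row %d: file not found: %s", bad[1],
                     df[[col]][bad[1]]))
    }
  }
  df
}

#' Write a simulated cohort to disk in the interchange formats
#'
#' Materializes a [simulate_cohort()] result as one spike file and one
#' torque file per trial plus a manifest, so the file-based pipeline can be
#' exercised end to end on synthetic data.
#'
#' @param cohort A `mu_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mu_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$trials, function(tr) {
    stem <- sprintf("%s_%s_%s", tr$subject_id, tr$side, tr$profile$kind)
    sp <- file.path(dir, paste0(stem, "_spikes.csv"))
    tq <- file.path(dir, paste0(stem, "_torque.csv"))
    write_spike_trains(tr$spikes, sp)
    write_torque(tr$torque, tq)
    subj <- cohort$subjects[cohort$subjects$subject_id == tr$subject_id, ]
    data.frame(subject_id = tr$subject_id, sex = subj$sex, side = tr$side,
               protocol = tr$profile$kind,
               spike_path = basename(sp), torque_path = basename(tq),
               mvc_nm = subj$mvc_nm, updrs_iii = subj$updrs_iii,
               stringsAsFactors = FALSE)
  })
  manifest <- rbind_rows(rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(format_num_df(manifest), mpath, row.names = FALSE,
                   quote = FALSE)
  invisible(mpath)
}
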