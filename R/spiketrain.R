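#' Construct a motor-unit spike train
#'
#' A spike train is the ordered sequence of discharge times of one decomposed
#' motor unit, together with its provenance (subject, body side, contraction
#' protocol) and the pulse-to-noise ratio (PNR) reported by the
#' decomposition, when available.
#'
#' @param times Strictly increasing discharge times in seconds, all >= 0.
#' @param unit_id Unit identifier (character scalar).
#' @param subject_id Subject identifier.
#' @param side `"more_affected"` or `"less_affected"`.
#' @param protocol `"ramp_hold"` or `"triangle"`.
#' @param pnr_db Pulse-to-noise ratio in dB, or `NA` when the decomposition
#'   did not report one.
#' @param segment Optional integer vector, one element per spike, marking
#'   segments separated by long pauses (filled in by [remove_isi_outliers()];
#'   defaults to a single segment).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id = "MU01", subject_id = "S01",
                        side = c("more_affected", "less_affected"),
                        protocol = c("ramp_hold", "triangle"),
                        pnr_db = NA_real_, segment = NULL) {
  side <- match.arg(side)
  protocol <- match.arg(protocol)
  times <- as.numeric(times)
  if (length(times) && any(!is.finite(times)))
    stop("spike times must be finite")
  if (length(times) && any(times < 0))
    stop("spike times must be nonnegative")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  if (is.null(segment)) segment <- rep(1L, length(times))
  stopifnot(length(segment) == length(times))
  structure(
    list(times = times, unit_id = as.character(unit_id),
         subject_id = as.character(subject_id), side = side,
         protocol = protocol, pnr_db = as.numeric(pnr_db),
         segment = as.integer(segment)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  span <- if (length(x$times)) sprintf("%.3f-%.3f s", min(x$times), max(x$times))
          else "empty"
  cat(sprintf("<spike_train> %s/%s/%s %s: %d spikes (%s), PNR %s dB\n",
              x$subject_id, x$side, x$protocol, x$unit_id, length(x$times),
              span, ifelse(is.na(x$pnr_db), "NA", format(x$pnr_db))))
  invisible(x)
}

#' Number of discharges in a spike train
#' @param x A `spike_train`.
#' @return Integer spike count.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "spike_train"))
  length(x$times)
}

#' Flatten spike trains to a tidy table
#'
#' One row per discharge with the columns of the on-disk interchange format:
#' `subject_id`, `side`, `protocol`, `unit_id`, `spike_time_s`, `pnr_db`.
#'
#' @param trains A list of `spike_train` objects (or a single one).
#' @return A data frame.
#' @export
spikes_to_table <- function(trains) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  rows <- lapply(trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(subject_id = tr$subject_id, side = tr$side,
               protocol = tr$protocol, unit_id = tr$unit_id,
               spike_time_s = tr$times, pnr_db = tr$pnr_db,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

#' Rebuild spike trains from a tidy table
#'
#' Inverse of [spikes_to_table()]: groups rows by
#' (`subject_id`, `side`, `protocol`, `unit_id`) and validates each train.
#'
#' @param df A data frame with the interchange columns.
#' @return A list of `spike_train` objects, ordered by group key.
#' @export
table_to_spikes <- function(df) {
  need <- c("subject_id", "side", "protocol", "unit_id", "spike_time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"pnr_db" %in% names(df)) df$pnr_db <- NA_real_
  key <- interaction(df$subject_id, df$side, df$protocol, df$unit_id,
                     drop = TRUE, lex.order = TRUE)
  lapply(split(df, key), function(g) {
    g <- g[order(g$spike_time_s), , drop = FALSE]
    spike_train(g$spike_time_s, unit_id = g$unit_id[1],
                subject_id = g$subject_id[1], side = g$side[1],
                protocol = g$protocol[1], pnr_db = g$pnr_db[1])
  })
}
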