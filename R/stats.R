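stat_result <- function(estimate, ci95, p_value, test, df = NA_real_) {
  stopifnot(length(ci95) == 2L, ci95[1] <= ci95[2] || any(is.na(ci95)),
            is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(estimate = estimate, ci95 = ci95, p_value = p_value,
                 test = test, df = df),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: estimate %.4g, 95%% CI [%.4g, %.4g], df %s, p = %.4g\n",
              x$test, x$estimate, x$ci95[1], x$ci95[2],
              format(x$df), x$p_value))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Two-sided Student t test with pooled variance (`df = n1 + n2 - 2`), the
#' convention used for between-sex comparisons of subject characteristics
#' and laterality indices. Accepts either raw samples or
#' (mean, SD, n) summaries per group; both routes go through the same
#' summary-statistic formulas.
#'
#' @param x,y Raw numeric samples (provide these, or the summaries below).
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries, used when `x`/`y` are
#'   `NULL`.
#' @return A `stat_result`: estimate is the mean difference (group 1 minus
#'   group 2) with its 95% CI, plus `t` statistic in `test` label and the
#'   pooled df.
#' @examples
#' pooled_t_test(mean1 = 57.6, sd1 = 9.0, n1 = 14,
#'               mean2 = 62.2, sd2 = 5.2, n2 = 13)
#' @export
pooled_t_test <- function(x = NULL, y = NULL,
                          mean1 = NULL, sd1 = NULL, n1 = NULL,
                          mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(is.numeric(x), is.numeric(y))
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean1 - mean2
  if (se == 0) {
    if (diff == 0)
      return(stat_result(0, c(0, 0), 1, "pooled t (t = 0)", df))
    stop("zero pooled variance with unequal means: degenerate input")
  }
  t_stat <- diff / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  crit <- stats::qt(0.975, df)
  stat_result(diff, diff + c(-1, 1) * crit * se, p,
              sprintf("pooled t (t = %.4g)", t_stat), df)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square with 1 degree of freedom and no continuity
#' correction, the convention used for comparing medication-usage
#' proportions between groups. Expected counts come from the table margins.
#'
#' @param tab A 2x2 matrix (or object coercible to one) of nonnegative
#'   counts; no margin may be zero.
#' @return A `stat_result`: estimate is the chi-square statistic; the CI is
#'   `NA` (not defined for this test).
#' @examples
#' chi_square_2x2(matrix(c(12, 12, 2, 1), nrow = 2)) # usage by sex
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (sum(tab) == 0) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a zero margin leaves the expected counts undefined")
  # the asymptotic Pearson statistic is the intended method even for small
  # expected counts, so the advisory warning is silenced
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  stat_result(unname(ct$statistic), c(NA_real_, NA_real_),
              unname(ct$p.value), "Pearson chi-square (no correction)",
              unname(ct$parameter))
}

#' Pearson correlation with t-transform p value
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values and
#'   nonzero variance.
#' @return A `stat_result`: estimate is `r` with its 95% CI (Fisher z), two-
#'   sided p from the t transform with `n - 2` df.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int)
        else c(NA_real_, NA_real_)
  stat_result(unname(ct$estimate), ci, unname(ct$p.value),
              "Pearson correlation", unname(ct$parameter))
}

#' Robust LOESS curve
#'
#' Locally weighted scatterplot smoothing: at each evaluation point a
#' weighted linear regression is fitted to the `span` fraction of nearest
#' neighbors with tricube weights, followed by robustifying bisquare
#' reweighting iterations so single outliers barely deflect the curve. Used
#' to visualize the recruitment-threshold/discharge-rate relationship.
#'
#' @param x,y Numeric vectors, `n >= 10`.
#' @param span Fraction of points in each local window (default 0.75).
#' @param degree Local polynomial degree; only 1 (local linear) is
#'   supported.
#' @param iterations Robustifying iterations (default 2).
#' @return A data frame with columns `x` (sorted unique x) and `fitted`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 1, iterations = 2) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            degree == 1, span > 0, span <= 1, iterations >= 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stop("at least 10 points are required")
  q <- ceiling(span * n)
  if (q < degree + 2)
    stop("span too small: local windows need at least degree + 2 points")
  robust_w <- rep(1, n)
  fit_at <- function(x0, rw) {
    d <- abs(x - x0)
    h <- sort(d, partial = q)[q]
    if (h == 0) return(stats::weighted.mean(y[d == 0], rw[d == 0]))
    w <- (1 - pmin(d / h, 1)^3)^3 * rw
    if (sum(w > 0) < 2 || stats::sd(x[w > 0]) == 0)
      return(stats::weighted.mean(y, w))
    fit <- stats::lm.wfit(cbind(1, x - x0), y, w)
    unname(fit$coefficients[1])
  }
  for (it in seq_len(iterations)) {
    fitted_all <- vapply(x, fit_at, numeric(1), rw = robust_w)
    res <- y - fitted_all
    s <- stats::median(abs(res))
    robust_w <- if (s > 0) pmax(0, 1 - (res / (6 * s))^2)^2 else rep(1, n)
  }
  xs <- sort(unique(x))
  data.frame(x = xs, fitted = vapply(xs, fit_at, numeric(1), rw = robust_w))
}

#' Aggregate unit metrics to subject-side summaries
#'
#' One row per subject and body side, carrying the unweighted mean over
#' that side's QC-passed units of each outcome (mean discharge rate, CV of
#' the ISI, unit-wise delta-F). Sides with zero surviving units are simply
#' absent. Mean discharge rate comes from ramp-hold trials and delta-F from
#' triangle trials, so the two inputs may cover different protocols.
#'
#' @param metrics A [unit_metrics()]-style data frame (all trials).
#' @param deltaf Optional unit-wise delta-F table with `subject_id`, `side`,
#'   `delta_f_pps`.
#' @param subjects Optional subject table (`subject_id`, plus e.g. `sex`,
#'   `updrs_iii`, `mvc_nm`) merged onto the result.
#' @return A data frame with `subject_id`, `sex`, `side`, `n_units`,
#'   `mean_dr_pps`, `cv_isi_pct`, `delta_f_pps` and any extra subject
#'   columns.
#' @export
aggregate_subject_side <- function(metrics, deltaf = NULL, subjects = NULL) {
  stopifnot(is.data.frame(metrics),
            all(c("subject_id", "side") %in% names(metrics)))
  key <- c("subject_id", "side")
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  cols <- intersect(c("mean_dr_pps", "cv_isi_pct", "rt_pct_mvc"),
                    names(metrics))
  agg <- stats::aggregate(metrics[cols], by = metrics[key], FUN = mean_na)
  cnt <- stats::aggregate(list(n_units = metrics$unit_id),
                          by = metrics[key], FUN = function(v)
                            length(unique(v)))
  out <- merge(agg, cnt, by = key)
  if ("sex" %in% names(metrics)) {
    sx <- unique(metrics[c("subject_id", "sex")])
    out <- merge(out, sx, by = "subject_id", all.x = TRUE)
  }
  if (!is.null(deltaf) && nrow(deltaf)) {
    dfa <- stats::aggregate(list(delta_f_pps = deltaf$delta_f_pps),
                            by = deltaf[key], FUN = mean_na)
    out <- merge(out, dfa, by = key, all.x = TRUE)
  } else out$delta_f_pps <- NA_real_
  if (!is.null(subjects))
    out <- merge(out, subjects, by = "subject_id", all.x = TRUE,
                 suffixes = c("", ".subj"))
  out[order(out$subject_id, out$side), , drop = FALSE]
}

#' Between-side laterality indices
#'
#' Per-subject differences between the more- and less-affected sides,
#' oriented so that each index is positive under the disease-typical
#' direction: discharge rate and ISI variability are elevated on the
#' more-affected side (`more - less`), while the PIC estimate is depressed
#' there (`less - more`).
#'
#' @param summaries An [aggregate_subject_side()] table.
#' @return A data frame with one row per subject having both sides:
#'   `subject_id`, `sex` (if present), `delta_dr_pps`, `delta_cv_pct`,
#'   `delta_delta_f_pps`.
#' @export
laterality <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("subject_id", "side") %in% names(summaries)))
  rows <- lapply(split(summaries, summaries$subject_id), function(g) {
    more <- g[g$side == "more_affected", , drop = FALSE]
    less <- g[g$side == "less_affected", , drop = FALSE]
    if (nrow(more) != 1L || nrow(less) != 1L) return(NULL)
    data.frame(
      subject_id = g$subject_id[1],
      sex = if ("sex" %in% names(g)) g$sex[1] else NA_character_,
      delta_dr_pps = more$mean_dr_pps - less$mean_dr_pps,
      delta_cv_pct = more$cv_isi_pct - less$cv_isi_pct,
      delta_delta_f_pps = less$delta_f_pps - more$delta_f_pps,
      stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}

#' Two-way mixed-effects model for a side-by-sex outcome
#'
#' Fits a linear mixed model with sex, side and their interaction as fixed
#' effects and a random intercept per subject (REML), optionally adding the
#' recruitment threshold as a covariate (used for the discharge-rate
#' outcome). Returns estimated marginal means with 95% CIs per sex-by-side
#' cell, pairwise contrasts, and the Type III tests of the fixed effects
#' (Satterthwaite df).
#'
#' @param data A data frame with columns `subject_id`, `sex`, `side`, the
#'   outcome, and the covariate if requested. Either subject-side aggregates
#'   (one row per subject and side, the default analysis level) or
#'   unit-level rows — the random intercept handles both.
#' @param outcome Name of the outcome column.
#' @param covariate Optional name of a covariate column (e.g.
#'   `"rt_pct_mvc"`).
#' @return A list of class `mixed_result`: `model` (the fitted
#'   `lmerModLmerTest`), `emmeans` (cell means data frame with `lower`/
#'   `upper` 95% limits), `contrasts` (pairwise contrast data frame),
#'   `anova` (Type III table), `interaction` (estimate, Wald 95% CI and
#'   Satterthwaite p for the sex-by-side interaction coefficient under
#'   treatment contrasts: the difference-in-differences of the second side
#'   level relative to the first, second sex level vs first, with factor
#'   levels in sorted order) and `singular` (logical: random-effect
#'   variance estimated at the boundary).
#' @export
fit_mixed_model <- function(data, outcome, covariate = NULL) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "sex", "side", outcome) %in% names(data)))
  data <- data[stats::complete.cases(data[c("subject_id", "sex", "side",
                                            outcome, covariate)]), ]
  data$sex <- factor(data$sex)
  data$side <- factor(data$side)
  if (nlevels(data$sex) < 2L || nlevels(data$side) < 2L)
    stop("both sexes and both sides must be represented")
  rhs <- "sex * side + (1 | subject_id)"
  if (!is.null(covariate)) rhs <- paste(covariate, "+", rhs)
  form <- stats::as.formula(paste(outcome, "~", rhs))
  model <- lmerTest::lmer(form, data = data, REML = TRUE)
  singular <- lme4::isSingular(model, tol = 1e-4)
  emm <- emmeans::emmeans(model, ~ sex * side)
  emm_df <- as.data.frame(emm)
  names(emm_df)[names(emm_df) == "lower.CL"] <- "lower"
  names(emm_df)[names(emm_df) == "upper.CL"] <- "upper"
  contrasts <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                               adjust = "none"))
  an <- stats::anova(model, type = 3)
  co <- summary(model)$coefficients
  int_row <- grep(":", rownames(co))
  wald <- co[int_row, "Estimate"] +
    c(-1, 1) * stats::qt(0.975, co[int_row, "df"]) * co[int_row, "Std. Error"]
  interaction <- stat_result(unname(co[int_row, "Estimate"]), wald,
                             unname(co[int_row, "Pr(>|t|)"]),
                             "sex x side interaction",
                             unname(co[int_row, "df"]))
  structure(list(model = model, emmeans = emm_df, contrasts = contrasts,
                 anova = an, interaction = interaction, singular = singular),
            class = "mixed_result")
}

#' @export
print.mixed_result <- function(x, ...) {
  cat("<mixed_result>\n")
  print(x$emmeans, ...)
  cat(sprintf("interaction: %.4g [%.4g, %.4g], p = %.4g%s\n",
              x$interaction$estimate, x$interaction$ci95[1],
              x$interaction$ci95[2], x$interaction$p_value,
              if (x$singular) " (singular random-effect fit)" else ""))
  invisible(x)
}

#' Calibration study for the two-way mixed-effects model
#'
#' Simulates subject-by-side outcome data with known effects and refits
#' [fit_mixed_model()] on each replicate to check (a) the type-I error of
#' the sex-by-side interaction test under a zero interaction and (b) the
#' coverage of its 95% CI under a nonzero interaction. The default scenario
#' mirrors the cohort design validated here: 14 female and 13 male
#' subjects, both sides each, between-subject SD 0.8, residual SD 0.5, and
#' an interaction of 1.5 (in the outcome's units, e.g. pps) assigned to the
#' female more-affected cell.
#'
#' Under treatment contrasts the fitted interaction coefficient for this
#' scenario equals minus the injected effect (the coefficient measures the
#' male-vs-female difference of the side contrast), so coverage is assessed
#' against `-interaction`.
#'
#' @param n_rep Number of replicates per scenario.
#' @param seed Seed from which the replicate seeds are drawn.
#' @param interaction Injected interaction magnitude.
#' @param n_female,n_male Subjects per sex.
#' @param subject_sd,residual_sd Variance components of the generator.
#' @return A list with `type1_rate` (share of null replicates with
#'   interaction p < 0.05), `coverage` (share of effect replicates whose
#'   95% CI covers the true coefficient), and `n_rep`.
#' @export
calibrate_mixed_model <- function(n_rep = 100, seed = 1, interaction = 1.5,
                                  n_female = 14, n_male = 13,
                                  subject_sd = 0.8, residual_sd = 0.5) {
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, 2L * n_rep)
  simulate_one <- function(s, inter) {
    set.seed(s)
    n <- n_female + n_male
    subj <- data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                       sex = rep(c("female", "male"), c(n_female, n_male)),
                       stringsAsFactors = FALSE)
    d <- merge(subj, data.frame(side = c("more_affected", "less_affected"),
                                stringsAsFactors = FALSE))
    b <- stats::rnorm(n, 0, subject_sd)
    names(b) <- subj$subject_id
    d$y <- 10 + 0.5 * (d$sex == "female") +
      0.3 * (d$side == "more_affected") +
      inter * (d$sex == "female") * (d$side == "more_affected") +
      b[d$subject_id] + stats::rnorm(nrow(d), 0, residual_sd)
    fit_mixed_model(d, "y")$interaction
  }
  hits <- 0L; covered <- 0L
  truth <- -interaction
  for (i in seq_len(n_rep)) {
    null_int <- simulate_one(rep_seeds[i], 0)
    hits <- hits + (null_int$p_value < 0.05)
    eff_int <- simulate_one(rep_seeds[n_rep + i], interaction)
    covered <- covered +
      (eff_int$ci95[1] <= truth && truth <= eff_int$ci95[2])
  }
  list(type1_rate = hits / n_rep, coverage = covered / n_rep, n_rep = n_rep)
}

#' Onion-skin association per sex-by-side stratum
#'
#' Pearson correlation between the recruitment threshold and mean discharge
#' rate within each sex-by-side stratum, with a robust LOESS curve for
#' visualization. A negative correlation is the classic onion-skin pattern:
#' earlier-recruited units discharge faster.
#'
#' @param metrics A [unit_metrics()]-style data frame with `sex`, `side`,
#'   `rt_pct_mvc` and `mean_dr_pps`.
#' @param span LOESS span.
#' @return A data frame with one row per stratum (`sex`, `side`, `n_units`,
#'   `r`, `p_value`), with the per-stratum LOESS curves in attribute
#'   `"loess"`.
#' @export
onion_skin_check <- function(metrics, span = 0.75) {
  stopifnot(all(c("sex", "side", "rt_pct_mvc", "mean_dr_pps") %in%
                  names(metrics)))
  ok <- stats::complete.cases(metrics[c("rt_pct_mvc", "mean_dr_pps")])
  metrics <- metrics[ok, , drop = FALSE]
  strata <- split(metrics, interaction(metrics$sex, metrics$side, drop = TRUE))
  curves <- list()
  rows <- lapply(strata, function(g) {
    if (nrow(g) < 3L) return(NULL)
    res <- pearson_r(g$rt_pct_mvc, g$mean_dr_pps)
    if (nrow(g) >= 10L)
      curves[[paste(g$sex[1], g$side[1], sep = ".")]] <<-
        loess_fit(g$rt_pct_mvc, g$mean_dr_pps, span = span)
    data.frame(sex = g$sex[1], side = g$side[1], n_units = nrow(g),
               r = res$estimate, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  attr(out, "loess") <- curves
  out
}
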