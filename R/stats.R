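# Paired research-versus-control statistics with normality-gated test
# choice, follow-up-interval stratification and clinical-covariate
# correlations.
#
# Normality is tested with the Lilliefors-corrected Kolmogorov-Smirnov test
# (parameters estimated from the sample make the naive KS anticonservative);
# the uncorrected one-sample KS against N(mean(x), sd(x)) is available by
# flag. Differences that pass normality at alpha go to the paired t-test,
# everything else to the Wilcoxon signed-rank test (exact null distribution
# up to n = 25 non-zero differences, normal approximation with continuity
# correction above; zero differences dropped per the standard signed-rank
# convention). No multiple-testing correction is applied by default;
# Benjamini-Hochberg can be switched on in the report stage.

#' Normality check for a sample
#'
#' @param x Numeric vector.
#' @param alpha Significance level for the normality decision. Default 0.05.
#' @param method `"lilliefors"` (default; Kolmogorov-Smirnov with the
#'   Lilliefors correction for estimated mean and sd) or `"ks"` (naive
#'   one-sample KS against `N(mean(x), sd(x))`).
#' @return List with `statistic`, `p_value`, `is_normal` (`p >= alpha`) and
#'   `testable`. Constant vectors or fewer than 5 observations are flagged
#'   non-testable (`is_normal = FALSE`), which routes comparisons to the
#'   Wilcoxon test.
#' @export
normality_check <- function(x, alpha = 0.05, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 5L || stats::sd(x) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                is_normal = FALSE, testable = FALSE))
  res <- if (method == "lilliefors") nortest::lillie.test(x)
         else suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       is_normal = res$p.value >= alpha, testable = TRUE)
}

#' Paired comparison of research and control values
#'
#' Computes differences `research - control` over complete pairs, gates the
#' test choice on a normality check of the differences, and runs either the
#' paired t-test or the Wilcoxon signed-rank test. All-zero differences are
#' reported as degenerate with `p = 1`.
#'
#' @param research,control Equal-length numeric vectors, one entry per
#'   subject; incomplete pairs are dropped (pairwise deletion).
#' @param alpha Significance level used for the normality gate. Default
#'   0.05.
#' @param parameter Label carried into the result. Default `""`.
#' @param normality_method Passed to [normality_check()].
#' @param test `"auto"` (normality-gated, the default) or an explicit
#'   `"paired_t"` / `"wilcoxon"` override.
#' @return List of class `comparison_result`: `parameter`, `n_pairs`,
#'   per-group `mean`/`sd`/`median`/`q1`/`q3`, `summary_type`
#'   (`"mean_sd"` or `"median_iqr"`), `test_used` (`"paired_t"`,
#'   `"wilcoxon_signed_rank"` or `"degenerate"`), `p_value`,
#'   `normality_p` and `degenerate`.
#' @export
compare_paired <- function(research, control, alpha = 0.05, parameter = "",
                           normality_method = c("lilliefors", "ks"),
                           test = c("auto", "paired_t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(research) != length(control))
    mgm_stop("research and control vectors must have equal length")
  ok <- !is.na(research) & !is.na(control)
  r <- research[ok]; cl <- control[ok]
  n <- length(r)
  if (n < 3L) mgm_degenerate_stop("fewer than 3 complete pairs")
  d <- r - cl
  summ <- function(v) list(mean = mean(v), sd = stats::sd(v),
                           median = stats::median(v),
                           q1 = unname(stats::quantile(v, 0.25)),
                           q3 = unname(stats::quantile(v, 0.75)))
  base <- list(parameter = parameter, n_pairs = n,
               research = summ(r), control = summ(cl))
  if (all(d == 0)) {
    return(structure(c(base, list(summary_type = "median_iqr",
                                  test_used = "degenerate", p_value = 1,
                                  statistic = NA_real_,
                                  normality_p = NA_real_, degenerate = TRUE)),
                     class = "comparison_result"))
  }
  nc <- normality_check(d, alpha = alpha, method = match.arg(normality_method))
  use_t <- switch(test, auto = isTRUE(nc$is_normal),
                  paired_t = TRUE, wilcoxon = FALSE)
  if (use_t) {
    tt <- stats::t.test(r, cl, paired = TRUE)
    res <- list(summary_type = "mean_sd", test_used = "paired_t",
                p_value = tt$p.value, statistic = unname(tt$statistic),
                normality_p = nc$p_value, degenerate = FALSE)
  } else {
    dz <- d[d != 0]
    exact <- length(dz) <= 25L
    wt <- suppressWarnings(stats::wilcox.test(dz, exact = exact, correct = !exact))
    res <- list(summary_type = "median_iqr", test_used = "wilcoxon_signed_rank",
                p_value = wt$p.value, statistic = unname(wt$statistic),
                normality_p = nc$p_value, degenerate = FALSE)
  }
  structure(c(base, res), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  fmt <- if (x$summary_type == "mean_sd")
    sprintf("research %.3f +/- %.3f vs control %.3f +/- %.3f",
            x$research$mean, x$research$sd, x$control$mean, x$control$sd)
  else
    sprintf("research %.3f (%.3f-%.3f) vs control %.3f (%.3f-%.3f)",
            x$research$median, x$research$q1, x$research$q3,
            x$control$median, x$control$q1, x$control$q3)
  cat(sprintf("%s [n=%d, %s]: %s, p = %.4g\n", x$parameter, x$n_pairs,
              x$test_used, fmt, x$p_value))
  invisible(x)
}

# Map short parameter names onto metrics-table columns.
parameter_column <- function(parameter) {
  cols <- c(height = "height_px", width = "width_px",
            tortuosity = "tortuosity", density = "density",
            vagueness = "vagueness")
  if (!parameter %in% names(cols))
    mgm_stop(sprintf("unknown parameter '%s'", parameter))
  unname(cols[parameter])
}

#' Extract per-subject paired values from a metrics table
#'
#' Uses the aggregate rows of a metrics table. For `level = "both"` each
#' eye's value is the unweighted mean of its upper- and lower-eyelid values
#' (missing if either is missing).
#'
#' @param metrics Metrics data frame (standard schema).
#' @param parameter One of `"height"`, `"width"`, `"tortuosity"`,
#'   `"density"`, `"vagueness"`.
#' @param level `"upper"`, `"lower"` or `"both"`.
#' @return Data frame with `subject_id`, `interval_months`, `research`,
#'   `control`.
#' @export
metrics_pairs <- function(metrics, parameter, level = c("both", "upper", "lower")) {
  level <- match.arg(level)
  col <- parameter_column(parameter)
  agg <- metrics[metrics$gland_id == "AGGREGATE", ]
  if (nrow(agg) == 0L) mgm_stop("metrics table has no aggregate rows")
  value_for <- function(sid, role) {
    sel <- agg[agg$subject_id == sid & agg$eye_role == role, ]
    if (level %in% c("upper", "lower")) {
      v <- sel[sel$eyelid == level, col]
      if (length(v) == 1L) v else NA_real_
    } else {
      vu <- sel[sel$eyelid == "upper", col]
      vl <- sel[sel$eyelid == "lower", col]
      if (length(vu) == 1L && length(vl) == 1L) (vu + vl) / 2 else NA_real_
    }
  }
  sids <- unique(agg$subject_id)
  data.frame(
    subject_id = sids,
    interval_months = vapply(sids, function(s)
      agg$interval_months[agg$subject_id == s][1], numeric(1)),
    research = vapply(sids, value_for, numeric(1), role = "research"),
    control = vapply(sids, value_for, numeric(1), role = "control"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Research-versus-control comparison table
#'
#' Runs [compare_paired()] for every parameter at every eyelid level,
#' mirroring the usual clinical reporting layout (upper, lower, both
#' eyelids).
#'
#' @inheritParams metrics_pairs
#' @param parameters Parameters to compare.
#' @param levels Eyelid levels.
#' @param alpha Normality-gate significance level.
#' @return Data frame with one row per level x parameter: group summaries,
#'   test used and p-value.
#' @export
compare_table <- function(metrics,
                          parameters = c("height", "width", "tortuosity",
                                         "density", "vagueness"),
                          levels = c("upper", "lower", "both"),
                          alpha = 0.05) {
  rows <- list()
  for (lev in levels) {
    for (par in parameters) {
      pr <- metrics_pairs(metrics, par, lev)
      cmp <- compare_paired(pr$research, pr$control, alpha = alpha,
                            parameter = par)
      rows[[length(rows) + 1L]] <- comparison_row(cmp, level = lev)
    }
  }
  do.call(rbind, rows)
}

comparison_row <- function(cmp, level = NA_character_) {
  data.frame(eyelid = level, parameter = cmp$parameter,
                   n_pairs = cmp$n_pairs,
                   research_mean = cmp$research$mean, research_sd = cmp$research$sd,
                   research_median = cmp$research$median,
                   research_q1 = cmp$research$q1, research_q3 = cmp$research$q3,
                   control_mean = cmp$control$mean, control_sd = cmp$control$sd,
                   control_median = cmp$control$median,
                   control_q1 = cmp$control$q1, control_q3 = cmp$control$q3,
                   summary_type = cmp$summary_type, test_used = cmp$test_used,
                   p_value = cmp$p_value, stringsAsFactors = FALSE)
}

#' Stratify paired comparisons by follow-up interval
#'
#' Bins subjects by the interval (in months) between the triggering disease
#' and the ocular diagnosis into (0, 3], (3, 6], (6, 12] and (12, Inf), and
#' compares research versus control within each bin. Bins with fewer than 3
#' complete pairs are reported descriptively without a p-value.
#'
#' @inheritParams metrics_pairs
#' @param breaks Right-closed bin edges in months. Default
#'   `c(0, 3, 6, 12, Inf)`.
#' @return Data frame with one row per bin.
#' @export
stratify_by_interval <- function(metrics, parameter,
                                 level = c("both", "upper", "lower"),
                                 breaks = c(0, 3, 6, 12, Inf)) {
  level <- match.arg(level)
  pr <- metrics_pairs(metrics, parameter, level)
  if (any(pr$interval_months < 0, na.rm = TRUE))
    mgm_stop("negative follow-up intervals")
  labels <- paste0(breaks[-length(breaks)], "-", breaks[-1])
  labels[length(labels)] <- paste0(">", breaks[length(breaks) - 1])
  bin <- cut(pr$interval_months, breaks = breaks, labels = labels, right = TRUE)
  rows <- list()
  for (b in labels) {
    sel <- pr[!is.na(bin) & bin == b & !is.na(pr$research) & !is.na(pr$control), ]
    n <- nrow(sel)
    if (n >= 3L) {
      cmp <- compare_paired(sel$research, sel$control, parameter = parameter)
      rows[[b]] <- cbind(data.frame(interval_bin = b), comparison_row(cmp, level))
    } else {
      rows[[b]] <- data.frame(
        interval_bin = b, eyelid = level, parameter = parameter, n_pairs = n,
        research_mean = if (n) mean(sel$research) else NA_real_,
        research_sd = if (n > 1) stats::sd(sel$research) else NA_real_,
        research_median = if (n) stats::median(sel$research) else NA_real_,
        research_q1 = NA_real_, research_q3 = NA_real_,
        control_mean = if (n) mean(sel$control) else NA_real_,
        control_sd = if (n > 1) stats::sd(sel$control) else NA_real_,
        control_median = if (n) stats::median(sel$control) else NA_real_,
        control_q1 = NA_real_, control_q3 = NA_real_,
        summary_type = "descriptive", test_used = "none",
        p_value = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate a morphology parameter with a clinical covariate
#'
#' Spearman rank correlation (robust to the skewed distributions typical of
#' these indices) between a per-subject parameter value and a clinical
#' covariate, within one group; Pearson is available by flag. Pairwise
#' deletion of incomplete observations.
#'
#' @inheritParams metrics_pairs
#' @param covariate `"tbut_s"` or `"tmh_mm"`.
#' @param group `"research"` or `"control"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `coefficient`, `p_value`, `n`, `method`.
#' @export
correlate_with_clinical <- function(metrics, parameter,
                                    covariate = c("tbut_s", "tmh_mm"),
                                    group = c("research", "control"),
                                    level = c("both", "upper", "lower"),
                                    method = c("spearman", "pearson")) {
  covariate <- match.arg(covariate)
  group <- match.arg(group)
  level <- match.arg(level)
  method <- match.arg(method)
  pr <- metrics_pairs(metrics, parameter, level)
  agg <- metrics[metrics$gland_id == "AGGREGATE" & metrics$eye_role == group, ]
  cov <- vapply(pr$subject_id, function(s) {
    v <- agg[agg$subject_id == s, covariate]
    if (length(v)) v[1] else NA_real_
  }, numeric(1))
  val <- pr[[group]]
  ok <- !is.na(val) & !is.na(cov)
  if (sum(ok) < 3L) mgm_degenerate_stop("fewer than 3 complete observations")
  if (stats::sd(cov[ok]) == 0) mgm_degenerate_stop("constant covariate")
  ct <- suppressWarnings(stats::cor.test(val[ok], cov[ok], method = method,
                                         exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       n = sum(ok), method = method)
}
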