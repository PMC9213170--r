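# Two-group cohort comparisons: mean +/- SD summaries, two-sample t tests
# for continuous indexes (pooled-variance Student form by default, Welch
# behind a flag) and Pearson chi-squared tests for 2x2 sign incidences
# (no continuity correction by default, Yates behind a flag). Significance
# is flagged at alpha = 0.05 per test; no multiplicity adjustment is applied
# by default, with Bonferroni/BH available.

default_continuous_indexes <- function() {
  c("age", "SBP", "DBP", "MAP", "LDL", "HDL", "TC", "TG",
    "WBC", "HGB", "RBC", "ANC", "ALC", "NLR")
}

default_sign_indexes <- function() {
  c("male", "blend_sign", "low_density_sign", "island_sign", "satellite_sign")
}

split_two_groups <- function(df, column, group) {
  if (!column %in% names(df)) abort_invalid(sprintf("no column '%s'", column))
  if (!group %in% names(df)) abort_invalid(sprintf("no group column '%s'", group))
  g <- df[[group]]
  keep <- !is.na(df[[column]]) & !is.na(g)
  g <- factor(g[keep])
  if (nlevels(g) != 2L) abort_invalid("group column must have exactly two levels")
  split(df[[column]][keep], g)
}

#' Per-group mean and standard deviation
#'
#' @param df Cohort `data.frame`.
#' @param column Continuous column to summarise.
#' @param group Two-level grouping column (default `"group"`).
#' @return `data.frame` with one row per group: `n`, `mean`, `sd` (sample SD,
#'   `n - 1` denominator).
#' @export
cohort_summarize <- function(df, column, group = "group") {
  parts <- split_two_groups(df, column, group)
  if (any(vapply(parts, length, 1L) < 2L)) {
    abort_invalid("each group needs at least 2 values")
  }
  data.frame(
    group = names(parts),
    n = vapply(parts, length, 1L),
    mean = vapply(parts, mean, 1),
    sd = vapply(parts, stats::sd, 1),
    row.names = NULL
  )
}

new_test_result <- function(column, test, statistic, df_free, p, summary, alpha = 0.05) {
  structure(
    list(column = column, test = test, statistic = unname(statistic),
         df = unname(df_free), p_value = unname(p), summary = summary,
         significant = p < alpha, alpha = alpha),
    class = "cohort_test_result"
  )
}

#' @export
print.cohort_test_result <- function(x, ...) {
  cat(sprintf("%s [%s]: statistic = %.4f, df = %.4g, p = %.4g %s\n",
              x$column, x$test, x$statistic, x$df, x$p_value,
              if (x$significant) sprintf("(significant at %.2g)", x$alpha) else ""))
  print(x$summary)
  invisible(x)
}

#' Two-sample t test between cohort groups
#'
#' Pooled-variance Student form by default (the convention in two-group
#' clinical reports); `welch = TRUE` drops the equal-variance assumption.
#'
#' @inheritParams cohort_summarize
#' @param welch Use Welch's unequal-variance form.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A `cohort_test_result` with the statistic, degrees of freedom,
#'   two-sided p value and per-group mean +/- SD summary.
#' @export
cohort_t_test <- function(df, column, group = "group", welch = FALSE, alpha = 0.05) {
  parts <- split_two_groups(df, column, group)
  if (any(vapply(parts, length, 1L) < 2L)) {
    abort_invalid("each group needs at least 2 values for a t test")
  }
  ht <- stats::t.test(parts[[1L]], parts[[2L]], var.equal = !welch)
  new_test_result(column, if (welch) "Welch t" else "Student t",
                  ht$statistic, ht$parameter, ht$p.value,
                  cohort_summarize(df, column, group), alpha)
}

#' Chi-squared test of a binary sign between cohort groups
#'
#' Pearson chi-squared on the 2x2 group-by-sign contingency table, without
#' continuity correction by default (`correct = TRUE` applies Yates).
#'
#' @inheritParams cohort_t_test
#' @param correct Apply Yates continuity correction.
#' @return A `cohort_test_result`; the summary holds per-group incidence.
#' @export
cohort_chi_square <- function(df, column, group = "group", correct = FALSE,
                              alpha = 0.05) {
  parts <- split_two_groups(df, column, group)
  tbl <- rbind(vapply(parts, function(v) sum(v != 0), 1),
               vapply(parts, function(v) sum(v == 0), 1))
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) {
    abort_invalid("all margins of the 2x2 table must be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(tbl, correct = correct))
  inc <- data.frame(
    group = names(parts),
    n = vapply(parts, length, 1L),
    incidence = vapply(parts, function(v) mean(v != 0), 1),
    row.names = NULL
  )
  new_test_result(column, if (correct) "chi-squared (Yates)" else "chi-squared",
                  ht$statistic, ht$parameter, ht$p.value, inc, alpha)
}

#' Run the full cohort comparison panel
#'
#' One Student t test per continuous index and one Pearson chi-squared test
#' per binary sign, with optional multiplicity adjustment of the p values.
#'
#' @param df Cohort `data.frame` (e.g. from [generate_cohort()] or
#'   [simulate_covariates()]).
#' @param continuous,categorical Columns to test; defaults are the standard
#'   blood-pressure/serology panel and the CT-sign columns, filtered to
#'   those present in `df`.
#' @param group Two-level grouping column.
#' @param welch,correct Passed to the underlying tests.
#' @param adjust Multiplicity adjustment method for `stats::p.adjust`
#'   (default `"none"`, matching the per-test convention of such reports).
#' @param alpha Significance level.
#' @return `data.frame` with one row per index: test, statistic, df,
#'   p value, adjusted p, per-group means/SDs (or incidences), significance.
#' @export
run_cohort_panel <- function(df, continuous = NULL, categorical = NULL,
                             group = "group", welch = FALSE, correct = FALSE,
                             adjust = "none", alpha = 0.05) {
  if (is.null(continuous)) continuous <- intersect(default_continuous_indexes(), names(df))
  if (is.null(categorical)) categorical <- intersect(default_sign_indexes(), names(df))
  rows <- list()
  for (col in continuous) {
    r <- cohort_t_test(df, col, group, welch = welch, alpha = alpha)
    rows[[col]] <- data.frame(
      index = col, type = "continuous", test = r$test,
      statistic = r$statistic, df = r$df, p_value = r$p_value,
      obs_mean = r$summary$mean[1], obs_sd = r$summary$sd[1],
      ctrl_mean = r$summary$mean[2], ctrl_sd = r$summary$sd[2],
      stringsAsFactors = FALSE
    )
  }
  for (col in categorical) {
    r <- cohort_chi_square(df, col, group, correct = correct, alpha = alpha)
    rows[[col]] <- data.frame(
      index = col, type = "categorical", test = r$test,
      statistic = r$statistic, df = r$df, p_value = r$p_value,
      obs_mean = r$summary$incidence[1], obs_sd = NA_real_,
      ctrl_mean = r$summary$incidence[2], ctrl_sd = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  out$significant <- out$p_adjusted < alpha
  out
}
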