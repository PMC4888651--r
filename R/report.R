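#' Two-sample Student's t-test (pooled variance)
#'
#' Two-tailed, unpaired, equal-variance t-test with `df = n_a + n_b - 2`,
#' the convention used for all group comparisons here. Delegates to
#' [stats::t.test()] with `var.equal = TRUE`, adding the degenerate-case
#' convention: two groups with zero pooled variance and equal means give
#' `t = 0, p = 1`; zero pooled variance with unequal means is an error.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return An object of class `oct_ttest`: list with `t_statistic`,
#'   `p_value`, `df`, `mean_a`, `mean_b`, `n_a`, `n_b`. Supports [tidy()] and
#'   [glance()].
#' @examples
#' tt <- ttest_two_sample(c(1, 2, 3), c(11, 12, 13))
#' tidy(tt)
#' @export
ttest_two_sample <- function(group_a, group_b) {
  a <- as.numeric(group_a)
  b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs n >= 2.", class = "oct_validation_error")
  }
  if (anyNA(a) || anyNA(b)) abort("Groups must not contain NA.", class = "oct_validation_error")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  s2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  if (s2 == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t_statistic = 0, p_value = 1, df = df,
                  mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb)
      return(structure(res, class = "oct_ttest"))
    }
    abort("Zero pooled variance with unequal means: t is degenerate.",
          class = "oct_degenerate_variance")
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  structure(list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b),
                 n_a = na, n_b = nb),
            class = "oct_ttest")
}

#' @export
print.oct_ttest <- function(x, ...) {
  cat("Two-sample t (pooled): t = ", signif(x$t_statistic, 5),
      ", df = ", x$df, ", p = ", signif(x$p_value, 5), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy_octspheroid
#' @export
tidy.oct_ttest <- function(x, ...) {
  tibble(estimate = x$mean_a - x$mean_b, t_statistic = x$t_statistic,
         df = x$df, p_value = x$p_value, n_a = x$n_a, n_b = x$n_b)
}

#' @rdname tidy_octspheroid
#' @export
glance.oct_ttest <- function(x, ...) tidy(x)

#' Box-plot group summary
#'
#' Quartiles and whiskers per the standard box-plot rule: whiskers extend to
#' `Q3 + 1.5 * IQR` / `Q1 - 1.5 * IQR`, clamped to the most extreme data
#' points that are not outliers; points beyond are listed as outliers.
#'
#' @param values Numeric vector, length >= 1.
#' @param group_label Label carried into the row.
#' @param quantile_type Quantile convention passed to [stats::quantile()];
#'   default 7 (linear interpolation). Type 2 gives the classical
#'   halves convention (`1:8` -> 2.5, 4.5, 6.5).
#' @return One-row tibble of class `oct_group_summary`: `group_label`, `n`,
#'   `mean`, `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `quantile_type`, and `outliers` (list-column).
#' @export
summarize_group <- function(values, group_label = "group", quantile_type = 7) {
  v <- as.numeric(values)
  if (!length(v)) abort("`values` must be non-empty.", class = "oct_validation_error")
  if (anyNA(v)) abort("`values` must not contain NA.", class = "oct_validation_error")
  qs <- quantile(v, c(0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  out <- tibble(
    group_label = group_label, n = length(v), mean = mean(v),
    q1 = qs[1], median = qs[2], q3 = qs[3],
    whisker_low = min(inside), whisker_high = max(inside),
    quantile_type = as.integer(quantile_type),
    outliers = list(sort(v[v < lo_fence | v > hi_fence]))
  )
  class(out) <- c("oct_group_summary", class(out))
  out
}

#' Summarize arms of a longitudinal experiment
#'
#' Applies [summarize_group()] to one metric per treatment arm and day.
#'
#' @param records Tidy per-well tibble with `treatment`, `day` and the metric
#'   column.
#' @param metric Name of the metric column.
#' @param quantile_type Passed to [summarize_group()].
#' @return Tibble of group summaries with `treatment`, `day` and `metric`.
#' @export
summarize_arms <- function(records, metric, quantile_type = 7) {
  if (!metric %in% names(records)) {
    abort(paste0("Column '", metric, "' not found."), class = "oct_validation_error")
  }
  if (!"day" %in% names(records)) records$day <- 0
  combos <- dplyr::distinct(records, .data$treatment, .data$day)
  rows <- pmap(combos, function(treatment, day) {
    v <- records[records$treatment == treatment & records$day == day, ][[metric]]
    v <- v[is.finite(v)]
    if (!length(v)) return(NULL)
    s <- summarize_group(v, group_label = paste0(treatment, "/day", day),
                         quantile_type = quantile_type)
    mutate(s, treatment = treatment, day = day, metric = metric, .before = 1)
  })
  bind_rows(rows)
}

#' Per-day combination-therapy synergy table
#'
#' Operationalizes synergy as the combination arm exceeding both
#' monotherapies: per day and metric, the combination mean is compared with
#' the larger monotherapy mean (difference and pooled t-test against that
#' arm), and flagged when the difference is positive with `p < alpha`. No
#' multiple-testing correction is applied by default, matching pairwise
#' reporting; `p_adjust = "bonferroni"` is available.
#'
#' @param records Tidy per-well tibble with `treatment`, `day` and the metric
#'   columns.
#' @param metrics Character vector of metric column names.
#' @param combination Treatment label of the combination arm.
#' @param monotherapies Length-2 character vector of monotherapy labels.
#' @param alpha Significance level for the synergy flag.
#' @param p_adjust `"none"` (default) or `"bonferroni"` across the table.
#' @return Tibble of class `oct_synergy`: `day`, `metric`,
#'   `combination_mean`, `mono_best`, `mono_best_mean`, `difference`,
#'   `t_statistic`, `p_value`, `synergy`.
#' @export
synergy_table <- function(records, metrics = c("disruption_index", "apoptotic_density"),
                          combination = "combination",
                          monotherapies = c("PDT", "carboplatin"),
                          alpha = 0.05, p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (!"day" %in% names(records)) records$day <- 0
  missing_metrics <- setdiff(metrics, names(records))
  if (length(missing_metrics)) {
    abort(paste0("Metric column(s) missing: ", paste(missing_metrics, collapse = ", ")),
          class = "oct_validation_error")
  }
  days <- sort(unique(records$day))
  need <- c(combination, monotherapies)
  rows <- list()
  for (d in days) {
    rd <- records[records$day == d, ]
    absent <- setdiff(need, unique(rd$treatment))
    if (length(absent)) {
      abort(paste0("Day ", d, ": missing arm(s) ", paste(absent, collapse = ", "), "."),
            class = "oct_validation_error")
    }
    for (m in metrics) {
      pull_arm <- function(arm) {
        v <- rd[rd$treatment == arm, ][[m]]
        v[is.finite(v)]
      }
      comb <- pull_arm(combination)
      m1 <- pull_arm(monotherapies[1])
      m2 <- pull_arm(monotherapies[2])
      best <- if (mean(m1) >= mean(m2)) monotherapies[1] else monotherapies[2]
      best_vals <- if (best == monotherapies[1]) m1 else m2
      diff <- mean(comb) - mean(best_vals)
      tt <- tryCatch(ttest_two_sample(comb, best_vals),
                     oct_degenerate_variance = function(e) NULL)
      pv <- if (is.null(tt)) NA_real_ else tt$p_value
      ts <- if (is.null(tt)) NA_real_ else tt$t_statistic
      rows[[length(rows) + 1L]] <- tibble(
        day = d, metric = m, combination_mean = mean(comb),
        mono_best = best, mono_best_mean = mean(best_vals),
        difference = diff, t_statistic = ts, p_value = pv,
        synergy = FALSE)
    }
  }
  out <- bind_rows(rows)
  if (p_adjust == "bonferroni") out$p_value <- pmin(out$p_value * nrow(out), 1)
  out$synergy <- out$difference > 0 & !is.na(out$p_value) & out$p_value < alpha
  class(out) <- c("oct_synergy", class(out))
  out
}

#' @rdname tidy_octspheroid
#' @export
tidy.oct_synergy <- function(x, ...) as_tibble(x)
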