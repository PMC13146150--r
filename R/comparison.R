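# Paired statistical comparison of retraining cadences against the weekly
# reference: Shapiro-Wilk normality screen, Wilcoxon signed-rank tests with
# Bonferroni correction, matched-pairs rank-biserial effect sizes and
# conventional effect labels.

#' Shapiro-Wilk normality check
#'
#' @param series numeric vector (length 3 to 5000, per the test's domain).
#' @return list with `statistic`, `p_value`, and `skipped` (TRUE when the
#'   series is constant, for which the test is undefined).
#' @export
normality_check <- function(series) {
  series <- series[!is.na(series)]
  if (length(series) < 3L)
    stop_config("Shapiro-Wilk needs at least 3 observations")
  if (stats::sd(series) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, skipped = TRUE))
  t <- stats::shapiro.test(series)
  list(statistic = unname(t$statistic), p_value = t$p.value, skipped = FALSE)
}

#' Paired Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Two-sided signed-rank test on `weekly - other`, pairs aligned by position
#' (pseudo-week); zero differences are dropped by the Wilcoxon convention,
#' and incomplete pairs (either side `NA`) are dropped pairwise. The effect
#' size is the matched-pairs rank-biserial correlation
#' `r = (sum of positive ranks - sum of negative ranks) / total rank sum`,
#' signed so that positive values mean the weekly series has the larger
#' metric values. The exact signed-rank distribution is used for n <= 25
#' without ties; a normal approximation with tie correction otherwise.
#'
#' @param weekly metric series of the weekly (reference) cadence.
#' @param other equally long, pairwise-aligned series of another cadence.
#' @return list with `p_value`, `effect_size`, `n_pairs` (after dropping),
#'   `n_dropped`.
#' @export
paired_wilcoxon <- function(weekly, other) {
  if (length(weekly) != length(other))
    stop_config("paired series must have equal length")
  ok <- !is.na(weekly) & !is.na(other)
  d <- weekly[ok] - other[ok]
  nz <- d != 0
  n_dropped <- sum(!ok) + sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = 1, effect_size = 0, n_pairs = 0L,
                n_dropped = n_dropped))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0]); w_neg <- sum(r[d < 0])
  effect <- (w_pos - w_neg) / (n * (n + 1) / 2)
  exact <- n <= 25L && !any(duplicated(abs(d)))
  p <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = TRUE))$p.value
  list(p_value = p, effect_size = effect, n_pairs = n, n_dropped = n_dropped)
}

#' Conventional label for a rank-biserial effect size
#'
#' |r| < 0.2 Negligible, \[0.2, 0.5) Small, \[0.5, 0.8) Medium, >= 0.8 Large.
#'
#' @param effect_size signed effect size(s) in \[-1, 1\].
#' @param thresholds boundaries for Small/Medium/Large.
#' @return character vector of labels.
#' @export
label_effect <- function(effect_size, thresholds = c(0.2, 0.5, 0.8)) {
  if (any(abs(effect_size) > 1 + 1e-12))
    stop_config("|effect size| must be <= 1")
  c("Negligible", "Small", "Medium", "Large")[
    findInterval(abs(effect_size), thresholds) + 1L]
}

#' Comparison configuration
#'
#' @param alpha family-wise significance level.
#' @param n_comparisons number of cadences compared against weekly.
#' @param effect_thresholds Small/Medium/Large boundaries for |r|.
#' @return list with `alpha`, `n_comparisons`, `corrected_alpha`,
#'   `effect_thresholds`.
#' @export
comparison_config <- function(alpha = 0.05, n_comparisons = 9L,
                              effect_thresholds = c(0.2, 0.5, 0.8)) {
  list(alpha = alpha, n_comparisons = as.integer(n_comparisons),
       corrected_alpha = alpha / n_comparisons,
       effect_thresholds = effect_thresholds)
}

#' Cadence comparison table
#'
#' For every cadence and metric: mean (SD), median (IQR width), and — for
#' non-weekly cadences — the paired Wilcoxon p-value against weekly, the
#' signed rank-biserial effect size (positive = weekly larger) and its label.
#' Significance is decided at the Bonferroni-corrected level
#' `alpha / n_comparisons`. The weekly reference rows carry `NA` in the
#' comparison columns.
#'
#' @param weekly_metrics named list of `ed_weekly_metrics` data frames, one
#'   per cadence, sharing the pseudo-week index; must contain `"weekly"`.
#' @param metrics metric columns to compare (default `auroc`, `amdbe`).
#' @param config a [comparison_config()].
#' @return data.frame (`ed_comparison_table`), one row per cadence x metric,
#'   with attribute `config`. IQR is reported as the 75th-25th percentile
#'   width.
#' @export
build_comparison_table <- function(weekly_metrics,
                                   metrics = c("auroc", "amdbe"),
                                   config = comparison_config()) {
  if (!"weekly" %in% names(weekly_metrics))
    stop_config("the weekly cadence must be present as the reference")
  ref <- weekly_metrics[["weekly"]]
  cadences <- c("weekly", setdiff(names(weekly_metrics), "weekly"))
  rows <- list()
  for (cad in cadences) {
    wm <- weekly_metrics[[cad]]
    key <- match(wm$pseudo_week, ref$pseudo_week)
    for (m in metrics) {
      v <- wm[[m]]
      is_ref <- cad == "weekly"
      cmp <- if (is_ref) list(p_value = NA_real_, effect_size = NA_real_,
                              n_pairs = NA_integer_) else
        paired_wilcoxon(ref[[m]][key], v)
      rows[[length(rows) + 1L]] <- data.frame(
        cadence = cad, metric = m,
        mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
        median = stats::median(v, na.rm = TRUE),
        iqr = stats::IQR(v, na.rm = TRUE),
        n_weeks = sum(!is.na(v)),
        p_vs_weekly = cmp$p_value,
        significant = if (is_ref) NA else cmp$p_value < config$corrected_alpha,
        effect_size = cmp$effect_size,
        effect_label = if (is_ref) NA_character_ else
          label_effect(cmp$effect_size, config$effect_thresholds)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("ed_comparison_table", "data.frame")
  out
}

#' Render a comparison table as aligned text
#'
#' Mirrors the Mean (SD) / Median (IQR) / p vs. weekly / Effect size /
#' Effect label column layout. The sign convention (positive = weekly
#' larger) is stated in the header.
#'
#' @param table an `ed_comparison_table`.
#' @return character vector of lines, invisibly; printed as a side effect.
#' @export
format_comparison_table <- function(table) {
  fmt <- function(x, d = 3) ifelse(is.na(x), "N/A", formatC(x, digits = d, format = "f"))
  lines <- c(
    "Cadence x metric comparison vs weekly (effect > 0: weekly larger)",
    sprintf("%-12s %-6s %-16s %-16s %-12s %-8s %s",
            "Cadence", "Metric", "Mean (SD)", "Median (IQR)", "p vs weekly",
            "Effect", "Label"))
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    lines <- c(lines, sprintf(
      "%-12s %-6s %-16s %-16s %-12s %-8s %s",
      r$cadence, r$metric,
      sprintf("%s (%s)", fmt(r$mean), fmt(r$sd)),
      sprintf("%s (%s)", fmt(r$median), fmt(r$iqr)),
      fmt(r$p_vs_weekly), fmt(r$effect_size),
      ifelse(is.na(r$effect_label), "N/A", r$effect_label)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
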