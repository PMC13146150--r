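# Performance metrics: AMDBE, AUROC, Brier, calibration slope/intercept,
# expected calibration error, thresholded classification metrics, index of
# dispersion, and the per-pseudo-week rollup.

#' Absolute mean daily bed error (AMDBE)
#'
#' The mean over days of |expected beds - actual admissions|, where expected
#' beds is the day's sum of predicted admission probabilities. The package's
#' aggregate calibration / clinical-utility metric: it answers "by how many
#' beds per day is the forecast off, on average".
#'
#' @param forecasts an `ed_daily_forecast` (from [daily_rollup()]) or any
#'   data frame with `expected_beds` and `actual_admissions` columns.
#' @return mean absolute daily bed error, in beds.
#' @export
amdbe <- function(forecasts) {
  if (NROW(forecasts) == 0L) stop_config("amdbe needs at least one day")
  mean(abs(forecasts$expected_beds - forecasts$actual_admissions))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random admitted case
#' scores above a random discharged one, ties counted 1/2. Requires both
#' classes.
#'
#' @param probabilities predicted scores.
#' @param outcomes binary outcomes.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(probabilities, outcomes) {
  y <- as.integer(outcomes)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop_config("AUROC is undefined with a single outcome class")
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @inheritParams auroc
#' @return Brier score in \[0, 1\].
#' @export
brier <- function(probabilities, outcomes) {
  if (!length(probabilities)) stop_config("brier needs at least one prediction")
  mean((probabilities - as.numeric(outcomes))^2)
}

#' Calibration slope and intercept
#'
#' Slope: coefficient of a logistic refit of the outcome on the logit of the
#' predicted probability (1 = perfectly calibrated spread). Intercept:
#' calibration-in-the-large, the offset of a logistic refit with the slope
#' fixed at 1 (0 = no systematic over/under-prediction). Probabilities are
#' clipped to (1e-6, 1 - 1e-6) before the logit.
#'
#' @inheritParams auroc
#' @return named numeric vector `c(slope =, intercept =)`.
#' @export
calibration_slope_intercept <- function(probabilities, outcomes) {
  y <- as.integer(outcomes)
  if (length(unique(y)) < 2L)
    stop_config("calibration refit needs both outcome classes")
  lp <- logit(clip_prob(probabilities))
  slope_fit <- suppressWarnings(
    stats::glm(y ~ lp, family = stats::binomial()))
  int_fit <- suppressWarnings(
    stats::glm(y ~ offset(lp), family = stats::binomial()))
  if (!slope_fit$converged || !int_fit$converged)
    warning("calibration refit did not converge (possible separation); values reported as-is")
  c(slope = unname(stats::coef(slope_fit)[2]),
    intercept = unname(stats::coef(int_fit)[1]))
}

#' Expected calibration error
#'
#' Probabilities are cut into `n_bins` equal-width bins; ECE is the
#' bin-weighted mean of |mean predicted probability - observed event rate|.
#'
#' @inheritParams auroc
#' @param n_bins number of equal-width bins (default 10).
#' @return ECE in \[0, 1\].
#' @export
ece <- function(probabilities, outcomes, n_bins = 10L) {
  if (n_bins < 1L) stop_config("n_bins must be >= 1")
  if (!length(probabilities)) stop_config("ece needs at least one prediction")
  y <- as.numeric(outcomes)
  bin <- pmin(pmax(ceiling(probabilities * n_bins), 1L), n_bins)
  n <- length(probabilities)
  agg <- vapply(split(seq_len(n), bin), function(i)
    c(length(i) / n, abs(mean(probabilities[i]) - mean(y[i]))), numeric(2))
  sum(agg[1, ] * agg[2, ])
}

#' Thresholded classification metrics
#'
#' Confusion-matrix metrics at a fixed probability threshold. Metrics whose
#' denominator is empty (e.g. precision with no predicted positives) are
#' returned as `NA`, not 0.
#'
#' @inheritParams auroc
#' @param threshold classification threshold in (0, 1); default 0.5.
#' @return named vector: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `npv`, `f1`.
#' @export
threshold_metrics <- function(probabilities, outcomes, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop_config("threshold must be in (0, 1)")
  y <- as.integer(outcomes)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); prec <- div(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || (sens + prec) == 0) NA_real_ else
    2 * sens * prec / (sens + prec)
  c(accuracy = div(tp + tn, tp + fp + tn + fn),
    sensitivity = sens,
    specificity = div(tn, tn + fp),
    precision = prec,
    npv = div(tn, tn + fn),
    f1 = f1)
}

#' Index of dispersion
#'
#' Variance-to-mean ratio of daily counts; 1 under a Poisson model, above 1
#' for overdispersed volumes.
#'
#' @param mean mean daily count (> 0).
#' @param variance variance of daily counts.
#' @return `variance / mean`.
#' @export
dispersion_index <- function(mean, variance) {
  if (any(mean <= 0)) stop_config("dispersion index needs mean > 0")
  variance / mean
}

#' Dispersion summary of a daily-count series by period
#'
#' Mean, SD, variance and index of dispersion of daily counts, grouped by a
#' period label (e.g. calendar quarter).
#'
#' @param counts daily counts.
#' @param period period label per day (e.g. `"2021 Q3"`).
#' @return data.frame with one row per period.
#' @export
dispersion_summary <- function(counts, period) {
  dt <- data.table::data.table(n = as.numeric(counts), period = period)
  out <- dt[, list(mean = mean(n), sd = stats::sd(n), variance = stats::var(n)),
            by = "period"]
  out[, "index_of_dispersion" := out$variance / out$mean]
  as.data.frame(out)
}

#' Per-pseudo-week metric rollup
#'
#' Computes, for every pseudo-week of the test horizon, pooled discrimination
#' and calibration metrics over the week's presentations and AMDBE over the
#' week's daily forecasts. Weeks whose presentations are single-class get
#' `NA` discrimination/calibration entries (and are dropped pairwise by the
#' downstream cadence comparison).
#'
#' @param predictions data.frame with `date`, `probability`, `admitted`
#'   (as produced by [run_simulation()]).
#' @param forecasts matching `ed_daily_forecast`.
#' @param threshold classification threshold for the secondary metrics.
#' @return data.frame (`ed_weekly_metrics`), one row per pseudo-week.
#' @export
weekly_rollup <- function(predictions, forecasts, threshold = 0.5) {
  pw <- pseudo_week_of(predictions$date)
  fw <- pseudo_week_of(forecasts$date)
  weeks <- sort(unique(pw))
  rows <- lapply(weeks, function(w) {
    i <- which(pw == w)
    p <- predictions$probability[i]; y <- predictions$admitted[i]
    fc <- forecasts[fw == w, , drop = FALSE]
    two_class <- length(unique(y)) == 2L
    cal <- if (two_class) calibration_slope_intercept(p, y) else
      c(slope = NA_real_, intercept = NA_real_)
    tm <- threshold_metrics(p, y, threshold)
    data.frame(
      pseudo_week = w,
      week_start = min(predictions$date[i]),
      n = length(i),
      auroc = if (two_class) auroc(p, y) else NA_real_,
      amdbe = amdbe(fc),
      brier = brier(p, y),
      calibration_slope = cal[["slope"]],
      calibration_intercept = cal[["intercept"]],
      ece = ece(p, y),
      accuracy = tm[["accuracy"]],
      sensitivity = tm[["sensitivity"]],
      specificity = tm[["specificity"]],
      precision = tm[["precision"]],
      npv = tm[["npv"]],
      f1 = tm[["f1"]]
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$week_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ed_weekly_metrics", "data.frame")
  out
}
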