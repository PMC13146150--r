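# Covariate-drift diagnostics: domain classification between time windows,
# PCA reconstruction error against a reference window, and repeated-period
# performance monitoring.

# Columns that encode calendar position rather than case mix. They are
# excluded from drift comparisons by default: two windows from different
# months always differ in them, which would flag "drift" for any pair of
# windows regardless of the case-mix distribution.
.calendar_cols <- c("cyc_year_sin", "cyc_year_cos")

drop_calendar <- function(x) {
  keep <- setdiff(colnames(x), .calendar_cols)
  x[, keep, drop = FALSE]
}

#' Domain-classifier AUROC between two time windows
#'
#' Labels rows by window, fits a gradient-boosted classifier with
#' temporal-block cross-validation (contiguous blocks within each window)
#' and returns the pooled out-of-fold AUROC. ~0.5 means the windows are
#' indistinguishable; values near 1 indicate strong covariate shift.
#' Calendar-cycle columns are excluded (they identify the window trivially).
#'
#' @param x_ref,x_cmp feature matrices of the reference and comparison
#'   windows, rows in temporal order.
#' @param seed integer seed for the classifier.
#' @param n_folds number of temporal blocks (default 5).
#' @param min_rows minimum rows required per window.
#' @param nrounds,max_depth classifier size.
#' @return out-of-fold AUROC in \[0, 1\].
#' @export
domain_classifier_auroc <- function(x_ref, x_cmp, seed = 1L, n_folds = 5L,
                                    min_rows = 50L, nrounds = 40L,
                                    max_depth = 3L) {
  if (nrow(x_ref) < min_rows || nrow(x_cmp) < min_rows)
    stop_config("each window needs at least %d rows", min_rows)
  x_ref <- drop_calendar(unclass_matrix(x_ref))
  x_cmp <- drop_calendar(unclass_matrix(x_cmp))
  x <- rbind(x_ref, x_cmp)
  y <- c(rep(0L, nrow(x_ref)), rep(1L, nrow(x_cmp)))
  # temporal blocks: fold f = f-th contiguous slice of each window
  fold <- c(ceiling(seq_len(nrow(x_ref)) / nrow(x_ref) * n_folds),
            ceiling(seq_len(nrow(x_cmp)) / nrow(x_cmp) * n_folds))
  oof <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    dtr <- xgboost::xgb.DMatrix(x[tr, , drop = FALSE], label = y[tr], nthread = 1)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = max_depth,
                    eta = 0.3, tree_method = "hist", max_bin = 32,
                    seed = derive_seed(seed, f), nthread = 1),
      data = dtr, nrounds = nrounds, verbose = 0)
    oof[!tr] <- predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE],
                                                  nthread = 1))
  }
  auroc(oof, y)
}

#' PCA reconstruction-error drift ratio
#'
#' Standardises the reference window (its own means/SDs only), fits an
#' orthogonal linear projection of rank `n_components` on it, and returns
#' the ratio of mean squared reconstruction error, comparison over
#' reference. Ratios near 1 mean the comparison window lies in the same
#' linear subspace; above 1 indicates shift into directions the reference
#' did not span. Constant reference columns are dropped with a warning.
#'
#' @param x_ref,x_cmp numeric feature matrices.
#' @param n_components projection rank (< number of retained columns).
#' @return list with `ratio`, `mse_ref`, `mse_cmp`, `n_components`.
#' @export
reconstruction_drift <- function(x_ref, x_cmp, n_components = 5L) {
  x_ref <- drop_calendar(unclass_matrix(x_ref))
  x_cmp <- drop_calendar(unclass_matrix(x_cmp))
  ctr <- colMeans(x_ref)
  scl <- apply(x_ref, 2, stats::sd)
  keep <- scl > 1e-12
  if (!all(keep)) {
    warning(sprintf("dropping %d constant reference column(s): %s",
                    sum(!keep), paste(colnames(x_ref)[!keep], collapse = ", ")))
  }
  if (n_components >= sum(keep))
    stop_config("n_components must be smaller than the number of varying columns (%d)",
                sum(keep))
  std <- function(x) sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]),
                           2, scl[keep], "/")
  zr <- std(x_ref); zc <- std(x_cmp)
  v <- stats::prcomp(zr, center = FALSE, scale. = FALSE)$rotation[, seq_len(n_components), drop = FALSE]
  mse <- function(z) {
    resid <- z - (z %*% v) %*% t(v)
    mean(resid^2)
  }
  mse_ref <- mse(zr); mse_cmp <- mse(zc)
  list(ratio = mse_cmp / mse_ref, mse_ref = mse_ref, mse_cmp = mse_cmp,
       n_components = n_components)
}

# Single-feature domain-classifier AUROC: how well each feature alone
# separates the two windows (folded above 0.5 so direction is ignored).
feature_shift_scores <- function(x_ref, x_cmp) {
  x_ref <- drop_calendar(unclass_matrix(x_ref))
  x_cmp <- drop_calendar(unclass_matrix(x_cmp))
  y <- c(rep(0L, nrow(x_ref)), rep(1L, nrow(x_cmp)))
  vapply(colnames(x_ref), function(cn) {
    v <- c(x_ref[, cn], x_cmp[, cn])
    if (stats::sd(v) < 1e-12) return(0.5)
    a <- auroc(v, y)
    max(a, 1 - a)
  }, numeric(1))
}

#' Drift report between a reference and a comparison window
#'
#' Bundles the domain-classifier AUROC, the PCA reconstruction-error ratio
#' and per-feature shift scores (single-feature domain AUROC, folded to
#' \[0.5, 1\]).
#'
#' @inheritParams domain_classifier_auroc
#' @param ref_range,cmp_range optional date ranges recorded in the report.
#' @param n_components rank of the reconstruction projection.
#' @return object of class `ed_drift_report`.
#' @export
drift_report <- function(x_ref, x_cmp, seed = 1L, n_components = 5L,
                         ref_range = NULL, cmp_range = NULL) {
  rec <- reconstruction_drift(x_ref, x_cmp, n_components)
  structure(list(
    reference_window = ref_range %||% date_range(x_ref),
    comparison_window = cmp_range %||% date_range(x_cmp),
    domain_auroc = domain_classifier_auroc(x_ref, x_cmp, seed = seed),
    reconstruction_error_ratio = rec$ratio,
    shift_scores = sort(feature_shift_scores(x_ref, x_cmp), decreasing = TRUE)
  ), class = "ed_drift_report")
}

#' @export
print.ed_drift_report <- function(x, ...) {
  cat("<ed_drift_report>\n")
  cat(sprintf("  domain AUROC %.3f, reconstruction-error ratio %.3f\n",
              x$domain_auroc, x$reconstruction_error_ratio))
  top <- utils::head(x$shift_scores, 5)
  cat("  top shifted features:",
      paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a drift report to JSON
#'
#' @param report an `ed_drift_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_drift_report <- function(report, path) {
  jsonlite::write_json(
    list(reference_window = as.character(report$reference_window),
         comparison_window = as.character(report$comparison_window),
         domain_auroc = report$domain_auroc,
         reconstruction_error_ratio = report$reconstruction_error_ratio,
         shift_scores = as.list(report$shift_scores)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Repeated-period performance monitoring
#'
#' Aggregates a weekly metric series by period (default calendar year) and
#' reports each period's mean AUROC and AMDBE together with deltas against a
#' baseline period — the tabular analogue of plotting performance over time
#' to expose drift.
#'
#' @param weekly an `ed_weekly_metrics` data frame.
#' @param baseline period label used as baseline (default: first period).
#' @param period_of function mapping week-start dates to period labels
#'   (default: calendar year).
#' @return data.frame with per-period means and `d_auroc` / `d_amdbe` deltas.
#' @export
performance_monitor <- function(weekly, baseline = NULL,
                                period_of = function(d) format(d, "%Y")) {
  per <- period_of(as.Date(weekly$week_start))
  dt <- data.table::data.table(period = per, auroc = weekly$auroc,
                               amdbe = weekly$amdbe)
  agg <- dt[, list(n_weeks = .N,
                   auroc = mean(auroc, na.rm = TRUE),
                   amdbe = mean(amdbe, na.rm = TRUE)), by = "period"]
  data.table::setorder(agg, period)
  agg <- as.data.frame(agg)
  if (!nrow(agg)) stop_config("no periods to monitor")
  baseline <- baseline %||% agg$period[1]
  if (!baseline %in% agg$period)
    stop_config("baseline period %s not present", baseline)
  b <- agg[agg$period == baseline, ]
  agg$d_auroc <- agg$auroc - b$auroc
  agg$d_amdbe <- agg$amdbe - b$amdbe
  agg$baseline <- agg$period == baseline
  agg
}
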