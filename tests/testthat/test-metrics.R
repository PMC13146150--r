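# Metric suite: AMDBE, AUROC vs the pair-counting oracle, Brier, calibration,
# ECE, thresholded metrics, dispersion index, weekly rollup.

forecast_of <- function(errors) {
  data.frame(date = as.Date("2022-01-01") + seq_along(errors) - 1,
             expected_beds = 10 + errors, actual_admissions = rep(10, length(errors)),
             n_presentations = rep(50, length(errors)))
}

test_that("AMDBE is the mean absolute daily bed error", {
  expect_equal(amdbe(forecast_of(c(1.5, -3.0, 4.5, 3.0))), 3.0)
  expect_equal(amdbe(forecast_of(c(0, 0, 0))), 0)
  expect_equal(amdbe(forecast_of(2.2)), 2.2)  # single day: 10.2 vs 8 in effect
  expect_error(amdbe(forecast_of(numeric(0))), "at least one day")
  # scale property: scaling all daily errors by c scales AMDBE by c
  e <- c(1.2, -0.4, 3.3, -2.1)
  expect_equal(amdbe(forecast_of(3 * e)), 3 * amdbe(forecast_of(e)))
})

test_that("AUROC matches exhaustive pair counting on small inputs", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)),
               auroc_oracle(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 2)  # rounding forces ties regularly
    expect_equal(auroc(p, y), auroc_oracle(p, y))
  }
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "single outcome class")
})

test_that("AUROC is invariant under monotone transforms; AMDBE and Brier are not", {
  set.seed(7)
  p <- runif(200); y <- rbinom(200, 1, p)
  q <- plogis(3 * qlogis(p))  # strictly monotone distortion
  expect_equal(auroc(q, y), auroc(p, y))
  expect_false(isTRUE(all.equal(brier(q, y), brier(p, y))))
  d <- rep(as.Date("2022-03-01"), 200) + (1:200 %% 10)
  expect_false(isTRUE(all.equal(amdbe(daily_rollup(q, y, d)),
                                amdbe(daily_rollup(p, y, d)))))
})

test_that("Brier score follows its closed forms", {
  expect_equal(brier(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(brier(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier(c(0.8, 0.2), c(1, 0)), 0.04)
})

test_that("calibration slope/intercept recover injected distortions", {
  set.seed(123)
  n <- 1e5
  p <- plogis(rnorm(n, -1.2, 1.3))
  y <- rbinom(n, 1, p)
  cal <- calibration_slope_intercept(p, y)
  expect_equal(unname(cal["slope"]), 1, tolerance = 0.03)
  expect_equal(unname(cal["intercept"]), 0, tolerance = 0.03)
  # doubled logit spread: recovered slope ~ 0.5
  p2 <- plogis(2 * qlogis(p))
  cal2 <- calibration_slope_intercept(p2, y)
  expect_equal(unname(cal2["slope"]), 0.5, tolerance = 0.04)
  # uniform logit deflation by delta: intercept ~ delta
  delta <- 0.4
  p3 <- plogis(qlogis(p) - delta)
  cal3 <- calibration_slope_intercept(p3, y)
  expect_equal(unname(cal3["intercept"]), delta, tolerance = 0.05)
})

test_that("ECE follows the binned formula", {
  # perfectly calibrated within every bin
  p <- c(rep(0.25, 8), rep(0.75, 4))
  y <- c(rep(1, 2), rep(0, 6), rep(1, 3), 0)
  expect_equal(ece(p, y, n_bins = 2), 0)
  # maximal miscalibration
  expect_equal(ece(rep(1, 5), rep(0, 5)), 1.0)
  # two-bin hand-computed oracle: 20 points
  p2 <- c(rep(0.2, 12), rep(0.9, 8))
  y2 <- c(rep(1, 6), rep(0, 6), rep(1, 4), rep(0, 4))
  # bin1: w=0.6, |0.2-0.5|=0.3; bin2: w=0.4, |0.9-0.5|=0.4 -> 0.18+0.16
  expect_equal(ece(p2, y2, n_bins = 2), 0.34)
  expect_error(ece(p2, y2, n_bins = 0), "n_bins")
})

test_that("thresholded metrics follow confusion-matrix arithmetic", {
  perf <- threshold_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_true(all(perf == 1))
  # all predicted negative: sensitivity 0, specificity 1, precision undefined
  none <- threshold_metrics(c(0.1, 0.2, 0.3), c(1, 0, 0), threshold = 0.5)
  expect_equal(none[["sensitivity"]], 0)
  expect_equal(none[["specificity"]], 1)
  expect_true(is.na(none[["precision"]]))
  # printed-style confusion counts: TP=45, FN=55, TN=95, FP=5 of 200
  p <- c(rep(0.9, 45), rep(0.1, 55), rep(0.1, 95), rep(0.9, 5))
  y <- c(rep(1, 100), rep(0, 100))
  m <- threshold_metrics(p, y)
  expect_equal(m[["accuracy"]], 140 / 200)
  expect_equal(m[["sensitivity"]], 45 / 100)
  expect_equal(m[["specificity"]], 95 / 100)
  expect_equal(m[["precision"]], 45 / 50)
  expect_equal(m[["npv"]], 95 / 150)
  expect_equal(m[["f1"]], 2 * 0.45 * 0.9 / (0.45 + 0.9))
  expect_error(threshold_metrics(p, y, threshold = 0), "threshold")
})

test_that("dispersion index is variance over mean", {
  expect_equal(round(dispersion_index(200.1, 483.1), 2), 2.41)
  expect_equal(round(dispersion_index(41.8, 47.2), 2), 1.13)
  set.seed(9)
  x <- rpois(20000, 30)
  expect_equal(dispersion_index(mean(x), var(x)), 1, tolerance = 0.05)
  expect_error(dispersion_index(0, 5), "mean")
})

test_that("weekly rollup matches direct metric calls and the pseudo-week grid", {
  set.seed(21)
  dates <- rep(as.Date("2022-01-23") + 0:10, each = 30)  # Jan W4 (23-31) + Feb W1
  p <- runif(length(dates)); y <- rbinom(length(dates), 1, p)
  preds <- data.frame(date = dates, probability = p, admitted = y)
  fc <- daily_rollup(p, y, dates)
  wm <- weekly_rollup(preds, fc)
  expect_equal(wm$pseudo_week, c("2022-01 W4", "2022-02 W1"))
  w4 <- dates >= as.Date("2022-01-23") & dates <= as.Date("2022-01-31")
  expect_equal(wm$auroc[1], auroc(p[w4], y[w4]))
  expect_equal(wm$amdbe[1], amdbe(fc[fc$date <= as.Date("2022-01-31"), ]))
  expect_equal(wm$brier[1], brier(p[w4], y[w4]))
  expect_identical(weekly_rollup(preds, fc), wm)
  # single-class week: discrimination marked missing, not an error
  y2 <- y; y2[!w4] <- 1L
  preds2 <- data.frame(date = dates, probability = p, admitted = y2)
  wm2 <- weekly_rollup(preds2, daily_rollup(p, y2, dates))
  expect_true(is.na(wm2$auroc[2]))
  expect_false(is.na(wm2$auroc[1]))
})
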