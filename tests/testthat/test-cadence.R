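# Pseudo-week grid, cadence schedules, daily rollup and the rolling
# simulation (leakage audit, determinism, cache purity).

test_that("pseudo-weeks partition every month with the printed day ranges", {
  pw <- pseudo_weeks("2021-01-01", "2021-12-31")
  jan <- pw[pw$month == as.Date("2021-01-01"), ]
  expect_equal(as.integer(format(jan$start, "%d")), c(1, 8, 16, 23))
  expect_equal(as.integer(format(jan$end, "%d")), c(7, 15, 22, 31))
  feb <- pw[pw$month == as.Date("2021-02-01"), ]
  expect_equal(as.integer(format(feb$end[4], "%d")), 28)
  # partition: every day of each month falls in exactly one pseudo-week
  for (m in c("2021-01-01", "2021-02-01")) {
    mo <- pw[pw$month == as.Date(m), ]
    days <- do.call(c, Map(seq, mo$start, mo$end, by = "day"))
    expect_identical(sort(unique(days)),
                     seq(as.Date(m), mo$end[4], by = "day"))
    expect_equal(length(days), length(unique(days)))
  }
  expect_equal(nrow(pw), 48)
})

test_that("cadence schedules imply the exact retrain-count ratios", {
  for (h in list(c("2021-01-01", "2021-12-31"),
                 c("2019-03-01", "2020-02-29"),
                 c("2021-07-01", "2023-06-30"))) {
    wk <- build_schedule("weekly", h[1], h[2])
    fn <- build_schedule("fortnightly", h[1], h[2])
    mo <- build_schedule("monthly", h[1], h[2])
    expect_equal(mo$retrain_count / wk$retrain_count, 0.25)
    expect_equal(fn$retrain_count / wk$retrain_count, 0.5)
    expect_true(all(mo$retrain_dates %in% fn$retrain_dates))
    expect_true(all(fn$retrain_dates %in% wk$retrain_dates))
    expect_false(is.unsorted(wk$retrain_dates, strictly = TRUE))
  }
  expect_equal(build_schedule("weekly", "2021-01-01", "2021-12-31")$retrain_count, 48)
  expect_equal(build_schedule("static", "2021-01-01", "2021-12-31")$retrain_count, 0)
  expect_equal(build_schedule("bimonthly", "2021-01-01", "2021-12-31")$retrain_count, 6)
  expect_equal(build_schedule("trimonthly", "2021-01-01", "2021-12-31")$retrain_count, 4)
  expect_equal(build_schedule("semiannual", "2021-01-01", "2021-12-31")$retrain_count, 2)
  expect_equal(build_schedule("annual", "2021-01-01", "2022-12-31")$retrain_count, 2)
  expect_equal(build_schedule("triennial", "2021-01-01", "2023-12-31")$retrain_count, 1)
  expect_error(build_schedule("daily", "2021-01-01", "2021-12-31"))
  expect_error(build_schedule("weekly", "2021-02-01", "2021-01-01"), "horizon")
})

test_that("daily rollup sums probabilities into expected beds", {
  fc <- daily_rollup(c(0.1, 0.4, 0.7), c(0, 1, 1), rep(as.Date("2022-01-03"), 3))
  expect_equal(fc$expected_beds, 1.2)
  expect_equal(fc$actual_admissions, 2)
  expect_equal(fc$n_presentations, 3)
  # days with no presentations are absent; zero probabilities sum to zero
  fc2 <- daily_rollup(c(0, 0), c(0, 0),
                      as.Date(c("2022-01-01", "2022-01-03")))
  expect_equal(nrow(fc2), 2)
  expect_equal(fc2$expected_beds, c(0, 0))
  expect_false(as.Date("2022-01-02") %in% fc2$date)
  expect_error(daily_rollup(c(0.1, 0.2), c(0), as.Date("2022-01-01")),
               "equal length")
})

sim_fixture <- function() {
  if (is.null(.fixture_cache[["sim"]])) {
    s <- small_stream(seed = 11, drift = 0)
    spec <- ensemble_spec(seed = 1, max_train_rows = 8000L,
                          gbt_params = list(nrounds = 20L))
    .fixture_cache[["sim"]] <- list(
      stream = s, spec = spec,
      sim = run_simulation(s, spec, cadences = c("monthly", "static"),
                           initial_train_years = 1))
  }
  .fixture_cache[["sim"]]
}

test_that("the simulation scores every test presentation and keeps temporal hygiene", {
  fx <- sim_fixture(); sim <- fx$sim
  d <- as.Date(fx$stream$arrival_datetime, tz = "UTC")
  n_test <- sum(d >= sim$test_start)
  for (cad in names(sim$cadences)) {
    preds <- sim$cadences[[cad]]$predictions
    expect_equal(nrow(preds), n_test)
    expect_true(all(preds$probability >= 0 & preds$probability <= 1))
  }
  # leakage audit from the retrain log: all training data strictly precedes
  # the fit date, validation sits between training and the fit date
  lg <- sim$log
  expect_true(all(lg$train_end < lg$fit_date))
  expect_true(all(lg$val_end < lg$fit_date))
  expect_true(all(lg$train_end <= lg$val_start))
  # static: a single fit at the test start
  expect_equal(unique(lg$fit_date[lg$cadence == "static"]), sim$test_start)
  expect_equal(sim$ledger$retrain_count[sim$ledger$cadence == "static"], 0)
})

test_that("cadence results are identical whether simulated jointly or alone", {
  fx <- sim_fixture()
  alone <- run_simulation(fx$stream, fx$spec, cadences = "static",
                          initial_train_years = 1)
  expect_identical(alone$cadences$static$predictions,
                   fx$sim$cadences$static$predictions)
})

test_that("the simulation is deterministic given stream, spec and seed", {
  fx <- sim_fixture()
  again <- run_simulation(fx$stream, fx$spec, cadences = c("monthly", "static"),
                          initial_train_years = 1)
  expect_identical(again$cadences$monthly$predictions,
                   fx$sim$cadences$monthly$predictions)
  expect_identical(again$cadences$static$forecasts,
                   fx$sim$cadences$static$forecasts)
})

test_that("a stream shorter than the initial training window is refused", {
  s <- small_stream(seed = 11, drift = 0)
  expect_error(run_simulation(s, ensemble_spec(), cadences = "static",
                              initial_train_years = 3),
               "too short")
})
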