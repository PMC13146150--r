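# Stacking ensemble: temporal hygiene, determinism, the monotone single-
# learner blend, leakage instrumentation, optional learners, persistence.

fit_fixture <- function(spec = ensemble_spec(seed = 1), drift = 0,
                        train_until = "2022-10-01", val_until = "2022-11-01") {
  s <- small_stream(seed = 11, drift = drift)
  x <- stream_features(s)
  d <- as.Date(s$arrival_datetime, tz = "UTC")
  tr <- which(d < as.Date(train_until))
  va <- which(d >= as.Date(train_until) & d < as.Date(val_until))
  te <- which(d >= as.Date(val_until))
  list(x = x, y = attr(x, "outcome"), d = d, tr = tr, va = va, te = te,
       spec = spec)
}

test_that("fitting refuses temporally overlapping windows", {
  f <- fit_fixture()
  xt <- subset_features(f$x, f$tr, f$d); xv <- subset_features(f$x, f$va, f$d)
  expect_error(
    fit_ensemble(f$spec, xt, f$y[f$tr], xv, f$y[f$va],
                 test_start = as.Date("2022-10-15")),
    "overlaps the declared test range")
  expect_error(
    fit_ensemble(f$spec, xv, f$y[f$va], xt, f$y[f$tr]),
    "must precede the validation range")
})

test_that("ensemble recovers the admission signal on held-out data", {
  f <- fit_fixture()
  m <- fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                    subset_features(f$x, f$va, f$d), f$y[f$va],
                    test_start = as.Date("2022-11-01"))
  p <- predict_proba(m, subset_features(f$x, f$te, f$d))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auroc(p, f$y[f$te]), 0.75)
})

test_that("identical data, spec and seed give identical predictions", {
  f <- fit_fixture()
  args <- list(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
               subset_features(f$x, f$va, f$d), f$y[f$va])
  m1 <- do.call(fit_ensemble, args)
  m2 <- do.call(fit_ensemble, args)
  xe <- subset_features(f$x, f$te, f$d)
  expect_identical(predict_proba(m1, xe), predict_proba(m2, xe))
})

test_that("single-base-learner blend is a monotone recalibration", {
  f <- fit_fixture()
  m <- fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                    subset_features(f$x, f$va, f$d), f$y[f$va])
  xe <- subset_features(f$x, f$te[1:2000], f$d)
  p_blend <- predict_proba(m, xe)
  p_base <- edcadence:::predict_base_learner(m$learners$gbt,
                                             edcadence:::unclass_matrix(xe))
  ord <- order(p_base)
  expect_true(all(diff(p_blend[ord]) >= -1e-12))
})

test_that("prediction is a pure vectorised function of the features", {
  f <- fit_fixture()
  m <- fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                    subset_features(f$x, f$va, f$d), f$y[f$va])
  xe <- subset_features(f$x, f$te[1:50], f$d)
  expect_identical(predict_proba(m, xe[c(7, 7), ]),
                   predict_proba(m, xe[7, , drop = FALSE])[c(1, 1)])
  expect_identical(predict_proba(m, xe[integer(0), , drop = FALSE]), numeric(0))
})

test_that("schema mismatches are refused with the offending column named", {
  f <- fit_fixture()
  m <- fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                    subset_features(f$x, f$va, f$d), f$y[f$va])
  other <- build_features(small_stream(seed = 11, drift = 0)[1:20, ],
                          feature_schema(embedding_dim = 2))
  expect_error(predict_proba(m, other), "schema mismatch.*emb_3")
})

test_that("validation rows never reach the oversampler", {
  f <- fit_fixture()
  seen <- NULL
  local_mocked_bindings(
    oversample_minority = function(x, y, k, seed, ...) {
      seen <<- nrow(x)
      list(x = x, y = y, n_synthetic = 0L)
    },
    .package = "edcadence")
  invisible(fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                         subset_features(f$x, f$va, f$d), f$y[f$va]))
  expect_equal(seen, min(length(f$tr), f$spec$max_train_rows))
})

test_that("single-class validation falls back to equal-weight averaging", {
  f <- fit_fixture()
  va1 <- f$va[f$y[f$va] == 1][1:30]
  expect_warning(
    m <- fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                      subset_features(f$x, va1, f$d), f$y[va1]),
    "equal-weight")
  expect_equal(m$meta$kind, "average")
  p <- predict_proba(m, subset_features(f$x, f$te[1:100], f$d))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("optional mlp and linear base learners stack alongside the trees", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("nnet")
  spec <- ensemble_spec(base_learners = c("gbt", "linear", "mlp"),
                        mlp_params = list(size = 3L, maxit = 30L),
                        max_train_rows = 4000L, seed = 2)
  f <- fit_fixture(spec)
  m <- fit_ensemble(spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                    subset_features(f$x, f$va, f$d), f$y[f$va])
  expect_setequal(names(m$learners), c("gbt", "linear", "mlp"))
  p <- predict_proba(m, subset_features(f$x, f$te[1:2000], f$d))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auroc(p, f$y[f$te[1:2000]]), 0.7)
  expect_error(ensemble_spec(base_learners = c("mlp", "linear")), "mandatory")
})

test_that("persisted ensembles predict identically after reload", {
  f <- fit_fixture()
  m <- fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                    subset_features(f$x, f$va, f$d), f$y[f$va])
  xe <- subset_features(f$x, f$te[1:500], f$d)
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(m, path)
  m2 <- load_ensemble(path)
  expect_equal(predict_proba(m2, xe), predict_proba(m, xe), tolerance = 1e-12)
})

test_that("permutation importance ranks the dominant predictor first", {
  f <- fit_fixture()
  m <- fit_ensemble(f$spec, subset_features(f$x, f$tr, f$d), f$y[f$tr],
                    subset_features(f$x, f$va, f$d), f$y[f$va])
  idx <- f$te[seq_len(min(2000, length(f$te)))]
  xe <- subset_features(f$x, idx, f$d)
  imp <- permutation_importance(m, xe, f$y[idx], seed = 1,
                                features = c("triage_4", "weekend", "emb_1"))
  expect_gt(imp[["triage_4"]], imp[["weekend"]])
})
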