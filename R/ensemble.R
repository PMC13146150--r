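# Stacking ensemble: a mandatory gradient-boosted-tree base learner plus
# optional multilayer-perceptron and penalised-linear learners, blended by a
# logistic meta-learner fitted on a temporally held-out validation split.

#' Ensemble specification
#'
#' @param base_learners character subset of `c("gbt", "mlp", "linear")`;
#'   `"gbt"` is mandatory. The default fits the gradient-boosted learner
#'   alone: the retraining-cadence findings do not depend on learner
#'   identity, and a single fast base learner keeps the rolling simulation
#'   (hundreds of refits) tractable on a desk machine.
#' @param gbt_params xgboost parameters (`nrounds`, `max_depth`, `eta`,
#'   `max_bin`, ...). Defaults are small and fixed: 60 rounds of depth-3
#'   histogram trees.
#' @param mlp_params `nnet` parameters (`size`, `decay`, `maxit`).
#' @param linear_params ridge-logistic parameters (`lambda`).
#' @param oversample apply minority oversampling ([oversample_minority()]) to
#'   the training partition (never to validation/test).
#' @param oversample_k SMOTE neighbourhood size (>= 1).
#' @param meta_penalty L2 penalty of the logistic meta-learner (0 = plain
#'   maximum likelihood).
#' @param max_train_rows cap on the training rows per fit; when the training
#'   window holds more, a seeded uniform subsample of this size is used
#'   (every epoch of the window stays eligible). Keeps the rolling
#'   simulation's hundreds of refits desk-tractable; `Inf` disables.
#' @param seed integer seed controlling oversampling, subsampling and any
#'   stochastic learner internals.
#' @return object of class `ed_ensemble_spec`.
#' @export
ensemble_spec <- function(base_learners = "gbt",
                          gbt_params = list(),
                          mlp_params = list(),
                          linear_params = list(),
                          oversample = TRUE,
                          oversample_k = 5L,
                          meta_penalty = 0,
                          max_train_rows = 50000L,
                          seed = 1L) {
  base_learners <- unique(base_learners)
  if (!"gbt" %in% base_learners)
    stop_config("the gradient-boosted base learner (\"gbt\") is mandatory")
  bad <- setdiff(base_learners, c("gbt", "mlp", "linear"))
  if (length(bad)) stop_config("unknown base learners: %s", paste(bad, collapse = ", "))
  if (oversample_k < 1L) stop_config("oversample_k must be >= 1")
  spec <- list(
    base_learners = base_learners,
    max_train_rows = max_train_rows,
    gbt_params = utils::modifyList(
      list(nrounds = 40L, max_depth = 3L, eta = 0.3, max_bin = 32L,
           min_child_weight = 5), gbt_params),
    mlp_params = utils::modifyList(
      list(size = 8L, decay = 1e-3, maxit = 80L), mlp_params),
    linear_params = utils::modifyList(list(lambda = 1e-3), linear_params),
    oversample = isTRUE(oversample),
    oversample_k = as.integer(oversample_k),
    meta_penalty = meta_penalty,
    seed = as.integer(seed)
  )
  class(spec) <- "ed_ensemble_spec"
  spec
}

fit_base_learner <- function(kind, x, y, params, seed) {
  switch(kind,
    gbt = {
      dtr <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      tree_method = "hist", max_bin = params$max_bin,
                      min_child_weight = params$min_child_weight,
                      seed = seed, nthread = 1),
        data = dtr, nrounds = params$nrounds, verbose = 0)
      list(kind = "gbt", model = booster)
    },
    linear = {
      if (!requireNamespace("glmnet", quietly = TRUE))
        stop_config("the \"linear\" base learner needs the glmnet package")
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            lambda = params$lambda, standardize = TRUE)
      list(kind = "linear", model = fit, lambda = params$lambda)
    },
    mlp = {
      if (!requireNamespace("nnet", quietly = TRUE))
        stop_config("the \"mlp\" base learner needs the nnet package")
      ctr <- colMeans(x)
      scl <- pmax(apply(x, 2, stats::sd), 1e-8)
      xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
      fit <- with_seed(seed, nnet::nnet(
        xs, y, size = params$size, decay = params$decay,
        maxit = params$maxit, entropy = TRUE, trace = FALSE,
        MaxNWts = 100000))
      list(kind = "mlp", model = fit, center = ctr, scale = scl)
    },
    stop_config("unknown base learner: %s", kind))
}

predict_base_learner <- function(learner, x) {
  switch(learner$kind,
    gbt = predict(learner$model, xgboost::xgb.DMatrix(x, nthread = 1)),
    linear = as.numeric(predict(learner$model, x, s = learner$lambda,
                                type = "response")),
    mlp = {
      xs <- sweep(sweep(x, 2, learner$center), 2, learner$scale, "/")
      as.numeric(predict(learner$model, xs))
    })
}

date_range <- function(x) {
  d <- attr(x, "dates")
  if (is.null(d)) NULL else range(d)
}

#' Fit the stacking ensemble
#'
#' Base learners are fitted on the (optionally oversampled) training
#' partition; the logistic meta-learner is then fitted on the base learners'
#' predicted probabilities over the untouched validation partition
#' (logit-transformed), so the blend is calibrated out-of-sample. With a
#' single base learner the blend reduces to a monotone recalibration of that
#' learner's probability.
#'
#' Temporal hygiene is enforced when date attributes are present (as built by
#' [build_features()]): training rows must precede validation rows, and both
#' must precede `test_start` when declared.
#'
#' @param spec an `ed_ensemble_spec`.
#' @param x_train,y_train training features/outcomes.
#' @param x_val,y_val validation features/outcomes (never oversampled).
#' @param test_start optional `Date`: first day of the test range the caller
#'   intends to score; fitting refuses data at or beyond it.
#' @return object of class `ed_ensemble`.
#' @export
fit_ensemble <- function(spec, x_train, y_train, x_val, y_val,
                         test_start = NULL) {
  stopifnot(inherits(spec, "ed_ensemble_spec"))
  tr_rng <- date_range(x_train)
  va_rng <- date_range(x_val)
  if (!is.null(test_start)) {
    test_start <- as.Date(test_start)
    if (!is.null(tr_rng) && tr_rng[2] >= test_start)
      stop_config("training data (up to %s) overlaps the declared test range (from %s)",
                  tr_rng[2], test_start)
    if (!is.null(va_rng) && va_rng[2] >= test_start)
      stop_config("validation data (up to %s) overlaps the declared test range (from %s)",
                  va_rng[2], test_start)
  }
  if (!is.null(tr_rng) && !is.null(va_rng) && tr_rng[2] > va_rng[1])
    stop_config("training range (up to %s) must precede the validation range (from %s)",
                tr_rng[2], va_rng[1])
  if (length(unique(y_train)) < 2L)
    stop_config("training outcomes are single-class")

  xt <- unclass_matrix(x_train); yt <- as.integer(y_train)
  if (is.finite(spec$max_train_rows) && nrow(xt) > spec$max_train_rows) {
    keep <- with_seed(derive_seed(spec$seed, "cap"),
                      sort(sample.int(nrow(xt), spec$max_train_rows)))
    xt <- xt[keep, , drop = FALSE]
    yt <- yt[keep]
  }
  n_synthetic <- 0L
  if (spec$oversample) {
    os <- oversample_minority(xt, yt, k = spec$oversample_k,
                              seed = derive_seed(spec$seed, "smote"))
    xt <- os$x; yt <- os$y; n_synthetic <- os$n_synthetic
  }

  learners <- lapply(spec$base_learners, function(kind)
    fit_base_learner(kind, xt, yt,
                     params = spec[[paste0(kind, "_params")]],
                     seed = derive_seed(spec$seed, kind)))
  names(learners) <- spec$base_learners

  base_val <- vapply(learners, predict_base_learner,
                     numeric(nrow(x_val)), x = unclass_matrix(x_val))
  base_val <- matrix(base_val, nrow = nrow(x_val))
  meta <- fit_meta(base_val, as.integer(y_val), spec$meta_penalty)

  structure(list(
    spec = spec,
    learners = learners,
    meta = meta,
    schema_hash = attr(x_train, "schema_hash"),
    feature_names = colnames(x_train),
    train_range = tr_rng,
    validation_range = va_rng,
    n_synthetic = n_synthetic
  ), class = "ed_ensemble")
}

unclass_matrix <- function(x) {
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  x
}

# Logistic blend over logit-transformed base probabilities. Single-class
# validation falls back to an equal-weight average with a warning.
fit_meta <- function(base_probs, y, penalty = 0) {
  z <- logit(clip_prob(base_probs))
  if (length(unique(y)) < 2L) {
    warning("validation outcomes are single-class; meta-learner falls back to equal-weight averaging")
    return(list(kind = "average", k = ncol(z)))
  }
  df <- as.data.frame(z)
  names(df) <- paste0("z", seq_len(ncol(z)))
  df$y <- y
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  list(kind = "logistic", coef = stats::coef(fit))
}

predict_meta <- function(meta, base_probs) {
  z <- logit(clip_prob(base_probs))
  if (meta$kind == "average") return(rowMeans(base_probs))
  co <- meta$coef
  co[is.na(co)] <- 0
  as.numeric(stats::plogis(co[1] + z %*% co[-1]))
}

#' Predict admission probabilities
#'
#' @param model an `ed_ensemble`.
#' @param x feature matrix conforming to the schema the model was fitted on;
#'   a mismatch raises an error naming the first offending column.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "ed_ensemble"))
  if (nrow(x) == 0L) return(numeric(0))
  hx <- attr(x, "schema_hash")
  if (!is.null(hx) && !is.null(model$schema_hash) && !identical(hx, model$schema_hash)) {
    off <- c(setdiff(model$feature_names, colnames(x)),
             setdiff(colnames(x), model$feature_names),
             if (length(model$feature_names) == length(colnames(x)))
               model$feature_names[model$feature_names != colnames(x)])[1]
    stop_config("feature schema mismatch (offending column: %s)", off %||% "<order>")
  }
  base <- vapply(model$learners, predict_base_learner,
                 numeric(nrow(x)), x = unclass_matrix(x))
  base <- matrix(base, nrow = nrow(x))
  p <- predict_meta(model$meta, base)
  pmin(pmax(p, 0), 1)
}

#' Persist / restore a fitted ensemble
#'
#' The artefact embeds the feature-schema hash; prediction refuses matrices
#' built under a different schema.
#'
#' @param model an `ed_ensemble`.
#' @param path file path (`.rds`).
#' @return `save_ensemble()` returns `path` invisibly; `load_ensemble()`
#'   returns the model.
#' @export
save_ensemble <- function(model, path) {
  raw <- model
  if (!is.null(raw$learners$gbt))
    raw$learners$gbt$model <- xgboost::xgb.save.raw(raw$learners$gbt$model)
  saveRDS(raw, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  raw <- readRDS(path)
  if (!is.null(raw$learners$gbt) && is.raw(raw$learners$gbt$model))
    raw$learners$gbt$model <- xgboost::xgb.load.raw(raw$learners$gbt$model)
  raw
}

#' @export
print.ed_ensemble <- function(x, ...) {
  cat("<ed_ensemble>\n")
  cat("  base learners:", paste(names(x$learners), collapse = ", "), "\n")
  if (!is.null(x$train_range))
    cat(sprintf("  trained on %s .. %s (validation %s .. %s)\n",
                x$train_range[1], x$train_range[2],
                x$validation_range[1], x$validation_range[2]))
  cat("  meta:", x$meta$kind, " synthetic rows:", x$n_synthetic, "\n")
  invisible(x)
}
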