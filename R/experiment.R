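# End-to-end experiment runner: generator -> rolling simulation -> metrics ->
# drift diagnostics -> cadence comparison, with artifact files, a structured
# log and a reproducibility manifest.

quarter_of <- function(dates) {
  dates <- as.Date(dates)
  paste(format(dates, "%Y"), paste0("Q", (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L))
}

#' Experiment configuration
#'
#' @param scenario an `ed_scenario` ([scenario_config()] / [desk_scenario()]).
#' @param ensemble an `ed_ensemble_spec`.
#' @param cadences cadence names to simulate (must include `"weekly"` for the
#'   comparison stage).
#' @param initial_train_years years reserved for initial training/validation
#'   before the test horizon (default 1).
#' @param output_dir directory for artifacts.
#' @param seed master seed; reseeds both the scenario and the ensemble.
#' @return list of class `ed_experiment_config`.
#' @export
experiment_config <- function(scenario = desk_scenario(),
                              ensemble = ensemble_spec(),
                              cadences = c("weekly", "monthly", "static"),
                              initial_train_years = 1,
                              output_dir = "ed-experiment",
                              seed = 1L) {
  bad <- setdiff(cadences, .cadences)
  if (length(bad)) stop_config("unknown cadences: %s", paste(bad, collapse = ", "))
  if (initial_train_years <= 0) stop_config("initial_train_years must be positive")
  scenario$seed <- as.integer(seed)
  ensemble$seed <- derive_seed(seed, "ensemble")
  structure(list(scenario = scenario, ensemble = ensemble,
                 cadences = cadences,
                 initial_train_years = initial_train_years,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "ed_experiment_config")
}

config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "output_dir")]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 89 + 1)) %% 4294967291)
}

log_line <- function(con, stage, event) {
  line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, event)
  message(line)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

#' Run a full cadence experiment
#'
#' Generates the scenario's stream, runs the rolling simulation for every
#' requested cadence, rolls metrics up by pseudo-week, computes drift
#' diagnostics (reference = initial training window, comparison = final
#' simulated year) and the cadence comparison table, and writes everything
#' under `config$output_dir`:
#' `stream.csv`, `forecasts_<cadence>.csv`, `predictions_<cadence>.csv`,
#' `weekly_metrics.csv`, `dispersion.csv`, `drift.json`, `comparison.csv`,
#' `compute_ledger.json`, `retrain_log.csv`, `manifest.json` and `run.log`.
#' Everything downstream is a pure function of the manifest (config + seed).
#'
#' @param config an `ed_experiment_config`.
#' @param write_stream_csv write the (large) stream CSV artifact
#'   (default `TRUE`).
#' @return the artifact bundle (list of objects and paths), invisibly.
#' @export
run_experiment <- function(config, write_stream_csv = TRUE) {
  stopifnot(inherits(config, "ed_experiment_config"))
  dir <- config$output_dir
  if (!dir.exists(dir) &&
      !suppressWarnings(dir.create(dir, recursive = TRUE)))
    stop_config("cannot create output directory %s", dir)
  probe <- file.path(dir, ".write-test")
  ok <- tryCatch({ writeLines("x", probe); TRUE }, error = function(e) FALSE)
  if (!ok) stop_config("output directory %s is not writable", dir)
  unlink(probe)

  logf <- file(file.path(dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  log_line(logf, "setup", sprintf("seed=%d config_hash=%s", config$seed,
                                  config_hash(config)))

  log_line(logf, "generate", "drawing presentation stream")
  stream <- generate_stream(config$scenario)
  stream <- inject_missingness(stream, list(postcode_class = 0.0075),
                               seed = derive_seed(config$seed, "missing"))
  if (write_stream_csv) write_stream(stream, file.path(dir, "stream.csv"))

  dates <- as.Date(stream$arrival_datetime, tz = "UTC")
  daily <- as.data.frame(table(dates))
  disp <- dispersion_summary(daily$Freq, quarter_of(as.Date(daily$dates)))
  utils::write.csv(disp, file.path(dir, "dispersion.csv"), row.names = FALSE)

  log_line(logf, "simulate", paste("cadences:", paste(config$cadences, collapse = ",")))
  sim <- run_simulation(stream, config$ensemble, config$cadences,
                        initial_train_years = config$initial_train_years)
  for (i in seq_len(nrow(sim$log)))
    log_line(logf, "retrain", sprintf("cadence=%s date=%s train=%s..%s",
                                      sim$log$cadence[i], sim$log$fit_date[i],
                                      sim$log$train_start[i], sim$log$train_end[i]))
  utils::write.csv(sim$log, file.path(dir, "retrain_log.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(stats::setNames(sim$ledger$retrain_count,
                                               sim$ledger$cadence)),
                       file.path(dir, "compute_ledger.json"), auto_unbox = TRUE)

  weekly <- list()
  for (cad in config$cadences) {
    res <- sim$cadences[[cad]]
    utils::write.csv(res$forecasts, file.path(dir, sprintf("forecasts_%s.csv", cad)),
                     row.names = FALSE)
    utils::write.csv(res$predictions, file.path(dir, sprintf("predictions_%s.csv", cad)),
                     row.names = FALSE)
    weekly[[cad]] <- weekly_rollup(res$predictions, res$forecasts)
  }
  wm_all <- do.call(rbind, lapply(names(weekly), function(cad)
    cbind(cadence = cad, weekly[[cad]])))
  utils::write.csv(wm_all, file.path(dir, "weekly_metrics.csv"), row.names = FALSE)

  log_line(logf, "drift", "domain classifier + reconstruction error")
  ref_idx <- which(dates < sim$test_start)
  cmp_idx <- which(dates > sim$test_end - 365L)
  x_all <- build_features(stream, sim$schema)
  cap <- function(idx, n = 6000L, tag = "win")
    if (length(idx) > n) idx[round(seq(1L, length(idx), length.out = n))] else idx
  drift <- withCallingHandlers(
    drift_report(x_all[cap(ref_idx), , drop = FALSE],
                 x_all[cap(cmp_idx), , drop = FALSE],
                 seed = derive_seed(config$seed, "drift"),
                 ref_range = range(dates[ref_idx]),
                 cmp_range = range(dates[cmp_idx])),
    warning = function(w) {
      log_line(logf, "drift", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_drift_report(drift, file.path(dir, "drift.json"))

  comparison <- NULL
  if ("weekly" %in% config$cadences && length(config$cadences) > 1L) {
    log_line(logf, "compare", "paired Wilcoxon vs weekly")
    comparison <- build_comparison_table(
      weekly, config = comparison_config(n_comparisons = length(config$cadences) - 1L))
    utils::write.csv(comparison, file.path(dir, "comparison.csv"), row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed, config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("edcadence")),
    r_version = as.character(getRversion()),
    cadences = config$cadences,
    test_start = as.character(sim$test_start),
    test_end = as.character(sim$test_end),
    n_presentations = nrow(stream),
    admission_prevalence = mean(stream$admitted)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_line(logf, "done", sprintf("artifacts in %s", dir))

  invisible(list(dir = dir, stream = stream, simulation = sim,
                 weekly_metrics = weekly, dispersion = disp,
                 drift = drift, comparison = comparison, manifest = manifest))
}

#' Render report artifacts from an experiment bundle
#'
#' Produces the AMDBE-over-time figure (one line per cadence, by
#' pseudo-week), the cadence comparison text table and the dispersion
#' summary. Missing bundle sections are skipped and listed. Idempotent.
#'
#' @param bundle the list returned by [run_experiment()].
#' @param file optional path for the figure (PNG); `NULL` skips writing.
#' @return list with `figure` (a ggplot), `comparison_lines`, `dispersion`
#'   and `missing` (names of skipped sections).
#' @export
render_report <- function(bundle, file = file.path(bundle$dir, "amdbe_over_time.png")) {
  missing <- character(0)
  fig <- NULL
  if (length(bundle$weekly_metrics)) {
    wm <- do.call(rbind, lapply(names(bundle$weekly_metrics), function(cad)
      cbind(cadence = cad, bundle$weekly_metrics[[cad]])))
    fig <- ggplot2::ggplot(wm, ggplot2::aes(
      x = .data$week_start, y = .data$amdbe, colour = .data$cadence)) +
      ggplot2::geom_line(alpha = 0.8) +
      ggplot2::labs(x = NULL, y = "AMDBE (beds)",
                    title = "Absolute mean daily bed error by pseudo-week",
                    colour = "cadence") +
      ggplot2::theme_minimal()
    if (!is.null(file)) {
      grDevices::png(file, width = 1400, height = 700, res = 150)
      print(fig)
      grDevices::dev.off()
    }
  } else missing <- c(missing, "weekly_metrics")

  lines <- NULL
  if (!is.null(bundle$comparison)) {
    lines <- utils::capture.output(format_comparison_table(bundle$comparison))
  } else missing <- c(missing, "comparison")

  disp <- bundle$dispersion
  if (is.null(disp)) missing <- c(missing, "dispersion")

  list(figure = fig, comparison_lines = lines, dispersion = disp,
       missing = missing)
}

#' Permutation feature importance
#'
#' Generic importance hook: the drop in AUROC when one feature column is
#' permuted. A stand-in for model-specific attribution methods; directional
#' use only.
#'
#' @param model an `ed_ensemble`.
#' @param x feature matrix.
#' @param y outcomes.
#' @param seed permutation seed.
#' @param features columns to score (default: all).
#' @return named numeric vector of AUROC drops, decreasing.
#' @export
permutation_importance <- function(model, x, y, seed = 1L,
                                   features = colnames(x)) {
  base <- auroc(predict_proba(model, x), y)
  with_seed(seed, {
    drops <- vapply(features, function(f) {
      xp <- x
      xp[, f] <- sample(xp[, f])
      base - auroc(predict_proba(model, xp), y)
    }, numeric(1))
    sort(drops, decreasing = TRUE)
  })
}
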