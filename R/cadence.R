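# Pseudo-week grid, retraining schedules and the rolling prospective
# simulation across cadences.

.cadences <- c("weekly", "fortnightly", "monthly", "bimonthly", "trimonthly",
               "semiannual", "annual", "biennial", "triennial", "static")
# retrain every k months at W1 (weekly/fortnightly handled separately)
.cadence_months <- c(monthly = 1, bimonthly = 2, trimonthly = 3,
                     semiannual = 6, annual = 12, biennial = 24, triennial = 36)

month_floor <- function(d) as.Date(format(as.Date(d), "%Y-%m-01"))

month_seq <- function(from, to) seq(month_floor(from), month_floor(to), by = "month")

#' Pseudo-week grid over a date range
#'
#' Each calendar month is divided into four pseudo-weeks: W1 = days 1--7,
#' W2 = days 8--15, W3 = days 16--22, W4 = day 23 to month-end. The grid
#' partitions every month (W2 spans 8 days; W4 absorbs the varying month
#' tail, e.g. days 23--31 in January but 23--28 in a non-leap February).
#'
#' @param start,end date range (inclusive).
#' @return data.frame with `label` (e.g. `"2021-07 W1"`), `month`, `index`,
#'   `start`, `end`, one row per pseudo-week whose start lies in the range.
#' @export
pseudo_weeks <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  months <- month_seq(start, end)
  grid <- do.call(rbind, lapply(months, function(m) {
    month_end <- seq(m, by = "month", length.out = 2)[2] - 1
    data.frame(
      month = m,
      index = c("W1", "W2", "W3", "W4"),
      start = m + c(0L, 7L, 15L, 22L),
      end = c(m + c(6L, 14L, 21L), month_end)
    )
  }))
  grid <- grid[grid$start >= start & grid$start <= end, , drop = FALSE]
  grid$label <- paste(format(grid$month, "%Y-%m"), grid$index)
  rownames(grid) <- NULL
  grid[, c("label", "month", "index", "start", "end")]
}

# Pseudo-week label for each date (used to key weekly metric rollups).
pseudo_week_of <- function(dates) {
  dates <- as.Date(dates)
  dom <- as.integer(format(dates, "%d"))
  idx <- c("W1", "W2", "W3", "W4")[findInterval(dom, c(1, 8, 16, 23))]
  paste(format(dates, "%Y-%m"), idx)
}

#' Retraining schedule implied by a cadence
#'
#' On the pseudo-week grid: weekly retrains at every pseudo-week start
#' (4/month), fortnightly at W1 and W3, monthly at W1, and the k-monthly
#' cadences (bimonthly ... triennial) at W1 of every k-th month counted from
#' the first month of the horizon. `static` never retrains. Over any
#' whole-month horizon the retrain counts therefore satisfy the exact
#' identities monthly = 25% of weekly and fortnightly = 50% of weekly.
#'
#' @param cadence one of `"weekly"`, `"fortnightly"`, `"monthly"`,
#'   `"bimonthly"`, `"trimonthly"`, `"semiannual"`, `"annual"`, `"biennial"`,
#'   `"triennial"`, `"static"`.
#' @param start,end the test horizon.
#' @return object of class `ed_cadence_schedule`: list with `cadence`,
#'   `retrain_dates` (strictly increasing `Date`s) and `retrain_count`.
#' @export
build_schedule <- function(cadence, start, end) {
  cadence <- match.arg(cadence, .cadences)
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop_config("empty horizon: end precedes start")
  grid <- pseudo_weeks(start, end)
  dates <- if (cadence == "static") {
    as.Date(character(0))
  } else if (cadence == "weekly") {
    grid$start
  } else if (cadence == "fortnightly") {
    grid$start[grid$index %in% c("W1", "W3")]
  } else {
    k <- .cadence_months[[cadence]]
    months <- month_seq(start, end)
    keep <- months[seq_along(months) %% k == 1L | k == 1L]
    grid$start[grid$index == "W1" & grid$month %in% keep]
  }
  structure(list(cadence = cadence, retrain_dates = dates,
                 retrain_count = length(dates)),
            class = "ed_cadence_schedule")
}

#' Daily bed-demand rollup
#'
#' Sums predicted admission probabilities and actual admissions per calendar
#' day: the model's expected bed requirement for the day versus the realised
#' one. Days with no presentations are absent from the output.
#'
#' @param probabilities predicted admission probabilities.
#' @param outcomes observed binary outcomes, aligned with `probabilities`.
#' @param dates calendar `Date` of each presentation, aligned likewise.
#' @return data.frame (`ed_daily_forecast`) with `date`, `expected_beds`,
#'   `actual_admissions`, `n_presentations`.
#' @export
daily_rollup <- function(probabilities, outcomes, dates) {
  if (length(probabilities) != length(outcomes) ||
      length(probabilities) != length(dates))
    stop_config("probabilities, outcomes and dates must have equal length")
  dates <- as.Date(dates)
  dt <- data.table::data.table(p = probabilities, y = as.numeric(outcomes),
                               date = dates)
  out <- dt[, list(expected_beds = sum(p), actual_admissions = sum(y),
                   n_presentations = .N), by = "date"]
  data.table::setorder(out, date)
  out <- as.data.frame(out)
  class(out) <- c("ed_daily_forecast", "data.frame")
  out
}

#' Rolling prospective simulation across retraining cadences
#'
#' Steps through the test horizon mimicking deployment: for each cadence the
#' model is fitted at the test start, refitted at every scheduled retrain
#' date using only data strictly before that date (expanding window, with the
#' `validation_days` immediately before the date held out as the stacking
#' validation split), and every test presentation is scored by the model
#' current on its arrival day. Cadences that share a retrain date share the
#' identical refit (same window, same derived seed), so the computation is
#' cached across cadences; the compute ledger still accounts each cadence's
#' scheduled retrains separately.
#'
#' @param stream an `ed_stream` covering initial training plus the test
#'   horizon.
#' @param spec an `ed_ensemble_spec`.
#' @param cadences character vector of cadence names.
#' @param initial_train_years years of data before the test start reserved
#'   for initial training/validation.
#' @param test_end optional last test day (default: last day in the stream).
#' @param validation_days length of the held-out stacking validation split
#'   immediately before each (re)fit date.
#' @param schema optional `ed_schema` (defaults to the stream's embedding
#'   width).
#' @param sliding_years optional sliding-window length in years; `NULL`
#'   (default) keeps the expanding window.
#' @return object of class `ed_simulation`: per-cadence `forecasts`
#'   (daily rollup) and `predictions` (per-presentation), the compute
#'   `ledger`, the retrain `log`, and the horizon bounds.
#' @export
run_simulation <- function(stream, spec, cadences = c("weekly", "monthly", "static"),
                           initial_train_years = 1, test_end = NULL,
                           validation_days = 28L, schema = NULL,
                           sliding_years = NULL) {
  stopifnot(inherits(spec, "ed_ensemble_spec"))
  cadences <- vapply(cadences, function(cc) match.arg(cc, .cadences), "")
  dates_all <- as.Date(stream$arrival_datetime, tz = "UTC")
  first_day <- min(dates_all)
  test_start <- seq(first_day, by = paste(initial_train_years, "year"),
                    length.out = 2)[2]
  test_end <- if (is.null(test_end)) max(dates_all) else as.Date(test_end)
  if (test_start > test_end)
    stop_config("stream too short: no test days after %s years of initial training",
                initial_train_years)

  if (is.null(schema)) {
    d <- length(grep("^emb_", names(stream)))
    schema <- feature_schema(embedding_dim = d)
  }
  x_all <- build_features(stream, schema)
  y_all <- attr(x_all, "outcome")
  if (is.null(y_all)) stop_config("stream has no admitted outcome column")

  subset_x <- function(idx) {
    xs <- x_all[idx, , drop = FALSE]
    attr(xs, "dates") <- dates_all[idx]
    attr(xs, "schema_hash") <- schema$hash
    xs
  }

  fits <- new.env(parent = emptyenv())
  log_rows <- list()
  fit_at <- function(fit_date) {
    key <- as.character(fit_date)
    if (!is.null(fits[[key]])) return(fits[[key]])
    val_start <- fit_date - validation_days
    lo <- if (is.null(sliding_years))
      as.Date("1000-01-01") else fit_date - round(365.25 * sliding_years)
    idx_tr <- which(dates_all < val_start & dates_all >= lo)
    idx_va <- which(dates_all >= val_start & dates_all < fit_date)
    if (!length(idx_tr) || !length(idx_va))
      stop_config("no training/validation data before %s", fit_date)
    spec_d <- spec
    spec_d$seed <- derive_seed(spec$seed, key)
    model <- fit_ensemble(spec_d, subset_x(idx_tr), y_all[idx_tr],
                          subset_x(idx_va), y_all[idx_va],
                          test_start = fit_date)
    log_rows[[key]] <<- data.frame(
      fit_date = fit_date,
      train_start = min(dates_all[idx_tr]), train_end = max(dates_all[idx_tr]),
      val_start = min(dates_all[idx_va]), val_end = max(dates_all[idx_va]))
    fits[[key]] <- model
    model
  }

  test_idx <- which(dates_all >= test_start & dates_all <= test_end)
  results <- list()
  ledger <- list()
  usage <- list()
  for (cad in cadences) {
    sched <- build_schedule(cad, test_start, test_end)
    fit_dates <- sort(unique(c(test_start, sched$retrain_dates)))
    seg <- findInterval(dates_all[test_idx], fit_dates)
    prob <- numeric(length(test_idx))
    for (s in seq_along(fit_dates)) {
      rows <- which(seg == s)
      if (!length(rows)) next
      model <- fit_at(fit_dates[s])
      prob[rows] <- predict_proba(model, subset_x(test_idx[rows]))
    }
    preds <- data.frame(
      date = dates_all[test_idx],
      pseudo_week = pseudo_week_of(dates_all[test_idx]),
      probability = prob,
      admitted = y_all[test_idx]
    )
    results[[cad]] <- list(
      schedule = sched,
      predictions = preds,
      forecasts = daily_rollup(prob, y_all[test_idx], dates_all[test_idx])
    )
    ledger[[cad]] <- sched$retrain_count
    usage[[cad]] <- fit_dates
  }

  log_df <- do.call(rbind, log_rows[order(names(log_rows))])
  rownames(log_df) <- NULL
  retrain_log <- do.call(rbind, lapply(cadences, function(cad) {
    ld <- log_df[log_df$fit_date %in% usage[[cad]], , drop = FALSE]
    if (nrow(ld)) cbind(cadence = cad, ld) else NULL
  }))
  structure(list(
    cadences = results,
    ledger = data.frame(cadence = names(ledger),
                        retrain_count = unlist(ledger), row.names = NULL),
    log = retrain_log,
    test_start = test_start, test_end = test_end,
    spec = spec, schema = schema
  ), class = "ed_simulation")
}

#' @export
print.ed_simulation <- function(x, ...) {
  cat("<ed_simulation>", format(x$test_start), "..", format(x$test_end), "\n")
  print(x$ledger)
  invisible(x)
}
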