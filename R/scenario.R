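# Scenario configuration for the synthetic presentation-stream generator.

# Triage-priority mix and per-priority admission log-odds reflecting the strong
# acuity gradient typical of a tertiary paediatric ED (priority 1 almost always
# admitted, priority 5 almost never).
.triage_mix_default <- c(0.0064, 0.1090, 0.3000, 0.5756, 0.0090)
.triage_logit <- c(2.32, 0.25, -0.86, -2.47, -4.70)

# Chief-complaint categories: skewed frequencies and heterogeneous admission
# effects (log-odds offsets relative to the triage baseline).
.complaint_codes <- c(
  "resp", "injury", "gastro", "fever", "ent", "neuro",
  "msk", "derm", "mental_health", "cardiac", "endo", "other"
)
.complaint_prob <- c(0.20, 0.18, 0.12, 0.11, 0.09, 0.07,
                     0.07, 0.06, 0.04, 0.02, 0.02, 0.02)
.complaint_logit <- c(0.35, -0.30, 0.10, 0.15, -0.25, 0.40,
                      -0.35, -0.55, 0.60, 0.70, 0.45, 0.00)

# Hour-of-day arrival weights over the four triage shift bins
# [0,8), [8,14), [14,18), [18,24): late-morning and evening peaks.
.shift_prob <- c(0.108, 0.329, 0.245, 0.318)

#' Scenario configuration for the synthetic ED stream
#'
#' Bundles every knob of the synthetic presentation-stream generator. The
#' defaults emulate the summary statistics of a six-year tertiary paediatric
#' ED cohort: ~187 presentations/day with an austral-winter (August) peak and
#' January trough, negative-binomial daily counts with index of dispersion
#' well above 1, ~20% admission prevalence with a steep triage-priority
#' gradient, a pandemic-style volume trough in the second quarter of 2020,
#' and a combined covariate + concept changepoint at the start of 2022.
#'
#' @param start_date first calendar day of the stream (`Date` or string).
#' @param n_years integer number of simulated years (>= 1).
#' @param base_daily_mean expected presentations per day before seasonality.
#' @param seasonal_amplitude amplitude of the annual log-scale volume cycle
#'   (0.14 gives a ~15% August/annual-mean ratio).
#' @param overdispersion negative-binomial size parameter of daily counts;
#'   index of dispersion is approximately `1 + base_daily_mean/overdispersion`.
#' @param admission_base_rate target overall admission prevalence in (0, 1).
#' @param triage_mix probability vector over triage priorities 1--5
#'   (must sum to 1).
#' @param covariate_changepoint date after which the covariate distribution
#'   (triage mix, complaint mix, embedding mean) is tilted, or `NULL`.
#' @param concept_changepoint date after which the outcome model's
#'   coefficients shift, or `NULL`.
#' @param drift_magnitude non-negative scalar scaling both drift mechanisms;
#'   0 disables drift even when changepoints are set.
#' @param trough_window optional `list(start=, end=, multiplier=)` applying a
#'   volume multiplier inside a date interval (pandemic-style trough).
#' @param embedding_dim dimension of the Gaussian free-text embedding
#'   surrogate (0 disables it).
#' @param mean_visits expected presentations per latent patient over the
#'   horizon, driving the revisit/history process.
#' @param seed integer seed; identical config + seed gives an identical stream.
#' @return object of class `ed_scenario` (a validated list).
#' @seealso [generate_stream()], [desk_scenario()]
#' @export
scenario_config <- function(start_date = "2018-07-01",
                            n_years = 6,
                            base_daily_mean = 187,
                            seasonal_amplitude = 0.14,
                            overdispersion = 80,
                            admission_base_rate = 0.20,
                            triage_mix = .triage_mix_default,
                            covariate_changepoint = "2022-01-01",
                            concept_changepoint = "2022-01-01",
                            drift_magnitude = 1,
                            trough_window = list(start = "2020-04-01",
                                                 end = "2020-06-30",
                                                 multiplier = 0.7),
                            embedding_dim = 8,
                            mean_visits = 2.5,
                            seed = 1L) {
  cfg <- list(
    start_date = as.Date(start_date),
    n_years = as.integer(n_years),
    base_daily_mean = base_daily_mean,
    seasonal_amplitude = seasonal_amplitude,
    overdispersion = overdispersion,
    admission_base_rate = admission_base_rate,
    triage_mix = triage_mix / 1,
    covariate_changepoint = if (is.null(covariate_changepoint)) NULL else as.Date(covariate_changepoint),
    concept_changepoint = if (is.null(concept_changepoint)) NULL else as.Date(concept_changepoint),
    drift_magnitude = drift_magnitude,
    trough_window = trough_window,
    embedding_dim = as.integer(embedding_dim),
    mean_visits = mean_visits,
    seed = as.integer(seed)
  )
  validate_scenario(cfg)
  class(cfg) <- "ed_scenario"
  cfg
}

validate_scenario <- function(cfg) {
  if (is.na(cfg$start_date)) stop_config("start_date is not a valid date")
  if (is.na(cfg$n_years) || cfg$n_years < 1L)
    stop_config("n_years must be an integer >= 1 (got %s)", cfg$n_years)
  if (abs(sum(cfg$triage_mix) - 1) > 1e-9 || any(cfg$triage_mix < 0) ||
      length(cfg$triage_mix) != 5L)
    stop_config("triage_mix must be a length-5 probability vector summing to 1")
  if (!is.finite(cfg$admission_base_rate) ||
      cfg$admission_base_rate <= 0 || cfg$admission_base_rate >= 1)
    stop_config("admission_base_rate must lie in (0, 1)")
  if (cfg$drift_magnitude < 0) stop_config("drift_magnitude must be >= 0")
  if (cfg$overdispersion <= 0) stop_config("overdispersion must be > 0")
  if (cfg$embedding_dim < 0L) stop_config("embedding_dim must be >= 0")
  if (!is.null(cfg$trough_window)) {
    tw <- cfg$trough_window
    if (is.null(tw$start) || is.null(tw$end) || is.null(tw$multiplier))
      stop_config("trough_window needs start, end and multiplier")
    if (tw$multiplier <= 0) stop_config("trough multiplier must be > 0")
  }
  invisible(cfg)
}

#' Desk-scale drifting scenario
#'
#' A three-year scenario at ~150 presentations/day with a combined
#' covariate + concept changepoint halfway through the two-year test horizon
#' (1 Jan 2022, with the stream starting 1 Jul 2020). This is the default
#' study condition of the package's cadence experiments: the first year
#' supplies initial training/validation and the remaining two years are the
#' rolling test window.
#'
#' @param seed integer seed.
#' @param drift_magnitude drift scale; 0 yields the matched no-drift control.
#' @param ... further overrides passed to [scenario_config()].
#' @return an `ed_scenario`.
#' @export
desk_scenario <- function(seed = 1L, drift_magnitude = 1, ...) {
  scenario_config(
    start_date = "2020-07-01",
    n_years = 3,
    base_daily_mean = 150,
    covariate_changepoint = "2022-01-01",
    concept_changepoint = "2022-01-01",
    drift_magnitude = drift_magnitude,
    trough_window = NULL,
    seed = seed,
    ...
  )
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' Flat key-value files are accepted; keys mirror the arguments of
#' [scenario_config()]. Unknown keys are rejected.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return an `ed_scenario`.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- names(formals(scenario_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop_config("unknown scenario keys: %s", paste(bad, collapse = ", "))
  do.call(scenario_config, raw)
}

#' @export
print.ed_scenario <- function(x, ...) {
  cat("<ed_scenario>\n")
  cat(sprintf("  %s + %d years, ~%g presentations/day, admission rate %.2f\n",
              format(x$start_date), x$n_years, x$base_daily_mean,
              x$admission_base_rate))
  cat(sprintf("  drift magnitude %g (covariate %s, concept %s)\n",
              x$drift_magnitude,
              if (is.null(x$covariate_changepoint)) "none" else format(x$covariate_changepoint),
              if (is.null(x$concept_changepoint)) "none" else format(x$concept_changepoint)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
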