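# Synthetic ED presentation-stream generator.
#
# The stream emulates the statistical structure the cadence experiments rely
# on: overdispersed seasonal daily volumes, a ~20% admission prevalence with a
# steep triage gradient, self-consistent patient revisit history, an optional
# volume trough, and injectable covariate/concept drift at configurable
# changepoints.

# Outcome-model coefficients (log-odds scale). Triage carries most of the
# signal; the remaining effects reproduce the direction and rough size of the
# admission gradients seen across shift bins, age bands and remoteness in
# tertiary paediatric cohorts.
.shift_effect <- c(early_morning = 0.45, morning = 0.00,
                   afternoon = 0.10, evening = 0.18)
.coef_age_infant <- 0.25
.coef_age_teen <- 0.20
.coef_male <- 0.05
.coef_regional <- 1.30
.coef_adm12 <- 0.10
.coef_pres12 <- -0.02
.coef_frailty <- 0.50
.frailty_sd <- 0.60

# Drift composition at magnitude 1. Covariate drift tilts the triage and
# complaint mixes (acuity up, injuries down) and mean-shifts the embedding
# surrogate; concept drift shifts the outcome intercept and mid-acuity slopes.
# Sized so that a domain classifier separates pre/post windows with AUROC in
# the 0.92-0.99 band at magnitude 1 while calibration degrades more than
# discrimination.
.tilt_triage <- c(0.10, 0.25, 0.12, -0.12, -0.10)
.tilt_complaint <- c(0.5, -0.35, 0.1, 0.25, -0.25, 0.15, -0.2, -0.25, 0.6, 0.25, 0.15, 0)
.emb_shift_linked <- 0.10   # dims tied to the outcome: small, feeds calibration drift
.emb_shift_free <- 0.85     # dims free of the outcome: carries domain-classifier signal
.concept_intercept <- 0.20
.concept_midacuity <- 0.10
.concept_injury <- -0.15

embedding_beta <- function(d) {
  b <- numeric(d)
  if (d >= 1) b[1] <- 0.45
  if (d >= 2) b[2] <- 0.30
  b
}

seasonal_log_mean <- function(dates, cfg) {
  doy <- as.integer(format(dates, "%j"))
  # peak near 1 August (day 213): austral winter
  lm <- log(cfg$base_daily_mean) +
    cfg$seasonal_amplitude * cos(2 * pi * (doy - 213) / 365.25)
  if (!is.null(cfg$trough_window)) {
    tw <- cfg$trough_window
    inside <- dates >= as.Date(tw$start) & dates <= as.Date(tw$end)
    lm[inside] <- lm[inside] + log(tw$multiplier)
  }
  lm
}

sample_shift_hour <- function(n) {
  bin <- sample.int(4L, n, replace = TRUE, prob = .shift_prob)
  lo <- c(0, 8, 14, 18)[bin]
  hi <- c(8, 14, 18, 24)[bin]
  stats::runif(n, lo, hi)
}

sample_age <- function(n) {
  band <- sample.int(6L, n, replace = TRUE,
                     prob = c(0.155, 0.354, 0.230, 0.213, 0.047, 0.001))
  lo <- c(0, 1, 5, 10, 15, 18)[band]
  hi <- c(1, 5, 10, 15, 18, 19)[band]
  stats::runif(n, lo, hi)
}

tilted_prob <- function(p, tilt, magnitude) {
  w <- p * exp(magnitude * tilt)
  w / sum(w)
}

#' Generate a synthetic ED presentation stream
#'
#' Draws daily presentation counts from a negative binomial whose log-mean
#' carries an annual cosine cycle (August peak) and an optional trough
#' multiplier, then populates each presentation with triage-time covariates,
#' revisit-history counters from a latent patient process, an embedding
#' surrogate, and an admission outcome from a logistic model. After the
#' configured changepoints, the covariate distribution (triage/complaint mix,
#' embedding mean) and the outcome coefficients shift in proportion to
#' `drift_magnitude`. The overall intercept is centred so that, absent drift,
#' realised admission prevalence matches `admission_base_rate`.
#'
#' First-ever visits carry missing (`NA`) history fields
#' (`days_since_last_presentation` / `days_since_last_admission`); downstream
#' imputation handles them ([impute_records()]).
#'
#' @param config an `ed_scenario` from [scenario_config()].
#' @return a `data.frame` (also class `ed_stream`) ordered by
#'   `arrival_datetime`, one row per presentation, with the scenario attached
#'   as attribute `scenario`.
#' @export
generate_stream <- function(config) {
  validate_scenario(config)
  cfg <- config
  with_seed(cfg$seed, {
    n_days <- as.integer(round(cfg$n_years * 365.25))
    dates <- cfg$start_date + seq_len(n_days) - 1L
    mu <- exp(seasonal_log_mean(dates, cfg))
    counts <- stats::rnbinom(n_days, size = cfg$overdispersion, mu = mu)
    n <- sum(counts)
    date <- rep(dates, counts)

    cov_cp <- cfg$covariate_changepoint
    post_cov <- if (is.null(cov_cp) || cfg$drift_magnitude == 0)
      rep(FALSE, n) else date >= cov_cp

    hour <- sample_shift_hour(n)
    arrival <- as.POSIXct(date, tz = "UTC") + hour * 3600
    age <- sample_age(n)
    sex <- sample(c("female", "male", "other"), n, replace = TRUE,
                  prob = c(0.4499, 0.5500, 0.0001))

    triage <- integer(n)
    complaint <- character(n)
    n_pre <- sum(!post_cov)
    if (n_pre > 0) {
      triage[!post_cov] <- sample.int(5L, n_pre, replace = TRUE, prob = cfg$triage_mix)
      complaint[!post_cov] <- sample(.complaint_codes, n_pre, replace = TRUE,
                                     prob = .complaint_prob)
    }
    if (n - n_pre > 0) {
      triage[post_cov] <- sample.int(
        5L, n - n_pre, replace = TRUE,
        prob = tilted_prob(cfg$triage_mix, .tilt_triage, cfg$drift_magnitude))
      complaint[post_cov] <- sample(
        .complaint_codes, n - n_pre, replace = TRUE,
        prob = tilted_prob(.complaint_prob, .tilt_complaint, cfg$drift_magnitude))
    }

    postcode <- sample(c("metropolitan", "regional_remote"), n, replace = TRUE,
                       prob = c(0.949, 0.051))

    d <- cfg$embedding_dim
    emb <- if (d > 0) matrix(stats::rnorm(n * d), n, d) else NULL
    if (d > 0 && any(post_cov)) {
      shift <- c(rep(.emb_shift_linked, min(2L, d)),
                 rep(.emb_shift_free, max(0L, d - 2L))) * cfg$drift_magnitude
      emb[post_cov, ] <- sweep(emb[post_cov, , drop = FALSE], 2L, shift, "+")
    }

    # Latent patient process: visit counts per patient ~ 1 + geometric,
    # visits clustered around a per-patient episode centre, frailty shared
    # across a patient's visits.
    hist <- patient_history(arrival, triage, n, cfg)

    eta <- .triage_logit[triage] +
      .coef_age_infant * (age < 1) +
      .coef_age_teen * (age >= 15) +
      .coef_male * (sex == "male") +
      unname(.shift_effect[shift_bin(hour)]) +
      .coef_regional * (postcode == "regional_remote") +
      .complaint_logit[match(complaint, .complaint_codes)] +
      .coef_adm12 * pmin(hist$admissions_prior_12m, 6L) +
      .coef_pres12 * pmin(hist$presentations_prior_12m, 10L) +
      .coef_frailty * hist$frailty
    if (d > 0) eta <- eta + drop(emb %*% embedding_beta(d))

    # centre the intercept on the pre-drift regime so that realised
    # prevalence before any changepoint matches the target
    cps <- c(cfg$covariate_changepoint, cfg$concept_changepoint)
    pre_idx <- if (length(cps) && cfg$drift_magnitude > 0)
      which(date < min(cps)) else seq_len(n)
    if (!length(pre_idx)) pre_idx <- seq_len(n)
    offset <- stats::uniroot(
      function(c0) mean(stats::plogis(eta[pre_idx] + c0)) - cfg$admission_base_rate,
      interval = c(-10, 10), tol = 1e-10)$root
    eta <- eta + offset

    con_cp <- cfg$concept_changepoint
    if (!is.null(con_cp) && cfg$drift_magnitude > 0) {
      post_con <- date >= con_cp
      eta[post_con] <- eta[post_con] + cfg$drift_magnitude *
        (.concept_intercept +
           .concept_midacuity * (triage[post_con] %in% c(2L, 3L)) +
           .concept_injury * (complaint[post_con] == "injury"))
    }

    admitted <- stats::rbinom(n, 1L, stats::plogis(eta))

    out <- data.frame(
      arrival_datetime = arrival,
      age_years = age,
      sex = sex,
      triage_priority = triage,
      complaint_code = complaint,
      postcode_class = postcode,
      days_since_last_presentation = hist$days_since_last_presentation,
      days_since_last_admission = hist$days_since_last_admission,
      presentations_prior_12m = hist$presentations_prior_12m,
      admissions_prior_12m = hist$admissions_prior_12m,
      stringsAsFactors = FALSE
    )
    if (d > 0) {
      colnames(emb) <- paste0("emb_", seq_len(d))
      out <- cbind(out, as.data.frame(emb))
    }
    out$admitted <- admitted
    out <- out[order(out$arrival_datetime), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "scenario") <- cfg
    class(out) <- c("ed_stream", "data.frame")
    out
  })
}

# Revisit-history counters computed from a latent patient-id process. A
# patient-level frailty drives a provisional admission propensity for each
# visit; history counters are accumulated from strictly earlier visits of the
# same patient, so "days since last presentation" is exactly coherent with the
# stream's own timestamps. Each patient's visits cluster in time (episode
# centre + exponential revisit gaps, mean ~45 days, rank-matched to the
# realised arrival times), so inter-visit gaps and 12-month counters are
# stationary across the horizon after the first year's look-back burn-in.
patient_history <- function(arrival, triage, n, cfg) {
  p_stop <- 1 / cfg$mean_visits
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, 1L + stats::rgeom(max(1024L, ceiling(n / cfg$mean_visits / 4)), p_stop))
  }
  k <- which(cumsum(sizes) >= n)[1]
  sizes <- sizes[seq_len(k)]
  frailty_pat <- stats::rnorm(length(sizes), 0, .frailty_sd)

  t_days <- as.numeric(arrival) / 86400
  pid_visits <- rep.int(seq_along(sizes), sizes)[seq_len(n)]
  centre <- stats::runif(length(sizes), min(t_days), max(t_days))
  gaps <- stats::rexp(n, rate = 1 / 45)
  vt <- centre[pid_visits] + ave(gaps, pid_visits, FUN = function(g)
    cumsum(g) - g[1])
  pid <- integer(n)
  pid[order(t_days)] <- pid_visits[order(vt)]
  prov_eta <- -1.6 + 0.9 * (triage <= 2L) + frailty_pat[pid]
  prov_admit <- stats::rbinom(n, 1L, stats::plogis(prov_eta))

  dt <- data.table::data.table(i = seq_len(n), pid = pid, t = t_days, a = prov_admit)
  data.table::setorder(dt, pid, t)
  dt[, c("dsp", "dsa", "p12", "a12") := {
    m <- .N
    old <- findInterval(t - 365.25, t)
    ca <- cumsum(a)
    prev_ca <- c(0, ca[-m])
    old_ca <- c(0, ca)[old + 1L]
    la <- cummax(ifelse(a == 1L, t, -Inf))
    prev_la <- c(-Inf, la[-m])
    list(
      dsp = c(NA_real_, diff(t)),
      dsa = ifelse(is.finite(prev_la), t - prev_la, NA_real_),
      p12 = (seq_len(m) - 1L) - old,
      a12 = as.integer(prev_ca - old_ca)
    )
  }, by = "pid"]
  data.table::setorder(dt, i)
  list(
    days_since_last_presentation = dt$dsp,
    days_since_last_admission = dt$dsa,
    presentations_prior_12m = as.integer(dt$p12),
    admissions_prior_12m = dt$a12,
    frailty = frailty_pat[pid]
  )
}

# Fields that may be blanked by inject_missingness(). Age, sex, triage,
# embedding and outcome fields are never made missing.
.missable_fields <- c("complaint_code", "postcode_class",
                      "days_since_last_presentation",
                      "days_since_last_admission",
                      "presentations_prior_12m", "admissions_prior_12m")

#' Inject missingness into a presentation stream
#'
#' Independently blanks selected fields at per-field rates. Age, sex, triage
#' priority and embedding columns are never made missing, matching the
#' completeness pattern of triage-time data capture.
#'
#' @param stream an `ed_stream` (or compatible data frame).
#' @param rates named list/vector of missingness probabilities in \[0, 1\];
#'   names must be among `complaint_code`, `postcode_class`,
#'   `days_since_last_presentation`, `days_since_last_admission`,
#'   `presentations_prior_12m`, `admissions_prior_12m`.
#' @param seed integer seed for the blanking draws.
#' @return the stream with `NA`s injected.
#' @export
inject_missingness <- function(stream, rates, seed = 1L) {
  rates <- unlist(rates)
  bad <- setdiff(names(rates), .missable_fields)
  if (length(bad))
    stop_config("fields not eligible for missingness: %s", paste(bad, collapse = ", "))
  if (any(rates < 0 | rates > 1))
    stop_config("missingness rates must lie in [0, 1]")
  with_seed(seed, {
    for (f in names(rates)) {
      if (rates[[f]] == 0) next
      hit <- stats::runif(nrow(stream)) < rates[[f]]
      stream[[f]][hit] <- NA
    }
    stream
  })
}

#' Write / read a presentation stream as delimited text
#'
#' One row per presentation, comma-separated, ISO-8601 UTC timestamps.
#' `read_stream()` restores column types; the round trip preserves values to
#' second/1e-6 precision.
#'
#' @param stream an `ed_stream`.
#' @param path file path.
#' @return `write_stream()` returns `path` invisibly; `read_stream()` returns
#'   an `ed_stream`.
#' @export
write_stream <- function(stream, path) {
  data.table::fwrite(as.data.frame(stream), path, dateTimeAs = "ISO")
  invisible(path)
}

#' @rdname write_stream
#' @export
read_stream <- function(path) {
  x <- as.data.frame(data.table::fread(path, tz = "UTC"))
  x$arrival_datetime <- as.POSIXct(x$arrival_datetime, tz = "UTC")
  class(x) <- c("ed_stream", "data.frame")
  x
}
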