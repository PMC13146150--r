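# Deterministic feature engineering: derived temporal features, imputation
# rules and the fixed-order design matrix used by every learner.

#' Triage shift bin for an arrival hour
#'
#' Bins are half-open on the right: early morning \[0, 8), morning \[8, 14),
#' afternoon \[14, 18), evening \[18, 24), so each hour belongs to exactly one
#' bin and hour 8 is "morning".
#'
#' @param hour numeric vector of arrival hours in \[0, 24).
#' @return character vector of bin labels.
#' @export
shift_bin <- function(hour) {
  if (any(!is.finite(hour)) || any(hour < 0 | hour >= 24))
    stop_config("arrival hour must lie in [0, 24)")
  c("early_morning", "morning", "afternoon", "evening")[
    findInterval(hour, c(0, 8, 14, 18))]
}

#' Annual and weekly sine/cosine day cycles
#'
#' Encodes calendar position as smooth periodic pairs: the annual pair uses
#' `2*pi*day_of_year/365.25`, the weekly pair `2*pi*day_of_week/7`. Each pair
#' satisfies sin^2 + cos^2 = 1.
#'
#' @param dates a `Date` (or coercible) vector.
#' @param weekly include the weekly pair (default `TRUE`).
#' @return data.frame with columns `cyc_year_sin`, `cyc_year_cos` and, when
#'   `weekly`, `cyc_week_sin`, `cyc_week_cos`.
#' @export
day_cycle <- function(dates, weekly = TRUE) {
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  ang <- 2 * pi * doy / 365.25
  out <- data.frame(cyc_year_sin = sin(ang), cyc_year_cos = cos(ang))
  if (weekly) {
    dow <- as.integer(format(dates, "%u")) - 1L  # Monday = 0
    angw <- 2 * pi * dow / 7
    out$cyc_week_sin <- sin(angw)
    out$cyc_week_cos <- cos(angw)
  }
  out
}

is_weekend <- function(dates) as.integer(format(as.Date(dates), "%u")) >= 6L

#' Impute missing fields of presentation records
#'
#' Applies the triage-data imputation convention: missing categoricals get the
#' fallback label `"unknown"`; missing days-since-last-presentation/admission
#' become the patient's age in days (age * 365.25, i.e. "never seen before");
#' other missing numerics become 0. Age, sex and triage priority are required
#' and must be present. Idempotent.
#'
#' @param records data frame of presentation records (an `ed_stream` works).
#' @return the records with no missing values in model fields.
#' @export
impute_records <- function(records) {
  if (!"age_years" %in% names(records) || anyNA(records$age_years))
    stop_config("age_years is required and may not be missing")
  for (f in c("sex", "complaint_code", "postcode_class")) {
    if (!f %in% names(records)) next
    v <- as.character(records[[f]])
    v[is.na(v) | v == ""] <- "unknown"
    records[[f]] <- v
  }
  age_days <- records$age_years * 365.25
  for (f in c("days_since_last_presentation", "days_since_last_admission")) {
    if (!f %in% names(records)) next
    miss <- is.na(records[[f]])
    records[[f]][miss] <- age_days[miss]
  }
  for (f in c("presentations_prior_12m", "admissions_prior_12m")) {
    if (!f %in% names(records)) next
    records[[f]][is.na(records[[f]])] <- 0L
  }
  emb <- grep("^emb_", names(records), value = TRUE)
  for (f in emb) records[[f]][is.na(records[[f]])] <- 0
  records
}

#' Feature schema: the fixed design-matrix column order
#'
#' All learners and drift detectors share one schema so that matrices built
#' from different time windows are column-compatible. Categorical levels are
#' fixed here (not learned from data), with an explicit `"unknown"` level
#' absorbing unseen categories.
#'
#' @param embedding_dim number of embedding columns (0 for none).
#' @param weekly_cycle include the weekly sine/cosine pair.
#' @return object of class `ed_schema`: list with `columns` (ordered names),
#'   `complaint_levels`, `embedding_dim`, `weekly_cycle` and a content `hash`.
#' @export
feature_schema <- function(embedding_dim = 8L, weekly_cycle = TRUE) {
  complaint_levels <- c(.complaint_codes, "unknown")
  cols <- c(
    "age_years",
    "days_since_last_presentation", "days_since_last_admission",
    "presentations_prior_12m", "admissions_prior_12m",
    "cyc_year_sin", "cyc_year_cos",
    if (weekly_cycle) c("cyc_week_sin", "cyc_week_cos"),
    "weekend",
    "sex_male", "sex_other", "sex_unknown",
    paste0("triage_", 1:5),
    paste0("shift_", c("early_morning", "morning", "afternoon", "evening")),
    "postcode_regional_remote", "postcode_unknown",
    paste0("complaint_", complaint_levels),
    if (embedding_dim > 0) paste0("emb_", seq_len(embedding_dim))
  )
  sch <- list(columns = cols, complaint_levels = complaint_levels,
              embedding_dim = as.integer(embedding_dim),
              weekly_cycle = weekly_cycle)
  sch$hash <- schema_hash(sch)
  class(sch) <- "ed_schema"
  sch
}

schema_hash <- function(schema) {
  s <- paste(schema$columns, collapse = "|")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Export a feature schema as JSON
#'
#' Writes column names, types and source fields so external tabular files can
#' be validated against the expected layout.
#'
#' @param schema an `ed_schema`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_schema <- function(schema, path) {
  jsonlite::write_json(
    list(columns = schema$columns,
         complaint_levels = schema$complaint_levels,
         embedding_dim = schema$embedding_dim,
         weekly_cycle = schema$weekly_cycle,
         hash = schema$hash),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# Indicator columns for the given levels; values matching none (the reference
# level) yield all-zero rows.
one_hot <- function(values, levels, prefix) {
  m <- matrix(0, length(values), length(levels),
              dimnames = list(NULL, paste0(prefix, levels)))
  idx <- match(values, levels)
  keep <- !is.na(idx)
  m[cbind(which(keep), idx[keep])] <- 1
  m
}

#' Build the design matrix for a set of presentation records
#'
#' Deterministically maps imputed records to the numeric matrix defined by the
#' schema: numeric fields, sine/cosine day cycles, weekend flag, one-hot
#' indicators (exactly one triage and one shift indicator per row) and the
#' embedding block. Categories outside the schema collapse to the `"unknown"`
#' indicator. Records are imputed first via [impute_records()].
#'
#' @param records presentation records.
#' @param schema an `ed_schema`; defaults to a schema matching the records'
#'   embedding columns.
#' @return numeric matrix with `schema$columns` as columns, plus attributes
#'   `outcome` (the `admitted` vector, if present), `dates` (arrival dates)
#'   and `schema_hash`.
#' @export
build_features <- function(records, schema = NULL) {
  records <- impute_records(records)
  if (is.null(schema)) {
    d <- length(grep("^emb_", names(records)))
    schema <- feature_schema(embedding_dim = d)
  }
  n <- nrow(records)
  dates <- as.Date(records$arrival_datetime, tz = "UTC")
  hour <- as.numeric(records$arrival_datetime -
                       as.POSIXct(dates, tz = "UTC"), units = "hours")
  hour <- pmin(pmax(hour, 0), 24 - 1e-9)
  cyc <- day_cycle(dates, weekly = schema$weekly_cycle)

  sex <- as.character(records$sex)
  sex[!sex %in% c("female", "male", "other")] <- "unknown"
  postcode <- as.character(records$postcode_class)
  postcode[!postcode %in% c("metropolitan", "regional_remote")] <- "unknown"
  complaint <- as.character(records$complaint_code)
  complaint[!complaint %in% schema$complaint_levels] <- "unknown"
  bin <- shift_bin(hour)

  blocks <- cbind(
    age_years = records$age_years,
    days_since_last_presentation = records$days_since_last_presentation,
    days_since_last_admission = records$days_since_last_admission,
    presentations_prior_12m = as.numeric(records$presentations_prior_12m),
    admissions_prior_12m = as.numeric(records$admissions_prior_12m),
    as.matrix(cyc),
    weekend = as.numeric(is_weekend(dates)),
    one_hot(sex, c("male", "other", "unknown"), "sex_")[, , drop = FALSE],
    one_hot(records$triage_priority, 1:5, "triage_"),
    one_hot(bin, c("early_morning", "morning", "afternoon", "evening"), "shift_"),
    one_hot(postcode, c("regional_remote", "unknown"), "postcode_"),
    one_hot(complaint, schema$complaint_levels, "complaint_")
  )
  if (schema$embedding_dim > 0) {
    emb_cols <- paste0("emb_", seq_len(schema$embedding_dim))
    missing_cols <- setdiff(emb_cols, names(records))
    for (mc in missing_cols) records[[mc]] <- 0
    blocks <- cbind(blocks, as.matrix(records[emb_cols]))
  }
  x <- blocks[, schema$columns, drop = FALSE]
  attr(x, "outcome") <- if ("admitted" %in% names(records)) records$admitted else NULL
  attr(x, "dates") <- dates
  attr(x, "schema_hash") <- schema$hash
  x
}
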