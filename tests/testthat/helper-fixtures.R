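# Shared fixtures and independent oracles for the test suite.
# Streams are generated in code and cached per session so expensive draws
# happen once.

.fixture_cache <- new.env(parent = emptyenv())

# A small two-year stream (~40 presentations/day) without drift, used by
# feature/model tests where volume does not matter.
small_stream <- function(seed = 11L, drift = 0, ...) {
  key <- paste("small", seed, drift, ...)
  if (is.null(.fixture_cache[[key]])) {
    cfg <- scenario_config(
      start_date = "2021-01-01", n_years = 2, base_daily_mean = 40,
      covariate_changepoint = "2022-01-01", concept_changepoint = "2022-01-01",
      drift_magnitude = drift, trough_window = NULL, embedding_dim = 4,
      seed = seed, ...)
    .fixture_cache[[key]] <- generate_stream(cfg)
  }
  .fixture_cache[[key]]
}

# Matching feature matrix + helpers
stream_features <- function(stream) {
  key <- paste("feat", nrow(stream), sum(stream$admitted))
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_features(stream)
  .fixture_cache[[key]]
}

subset_features <- function(x, idx, dates = NULL) {
  xs <- x[idx, , drop = FALSE]
  if (!is.null(dates)) attr(xs, "dates") <- dates[idx]
  attr(xs, "schema_hash") <- attr(x, "schema_hash")
  xs
}

# Exhaustive pair-counting AUROC oracle: loops over every positive-negative
# pair, ties count 1/2.
auroc_oracle <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Exact two-sided paired signed-rank p-value by full enumeration of the 2^n
# sign assignments (no ties in |d| assumed).
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Distance from point q to segment [a, b]
point_segment_dist <- function(q, a, b) {
  ab <- b - a
  t <- sum((q - a) * ab) / max(sum(ab^2), 1e-300)
  t <- min(max(t, 0), 1)
  sqrt(sum((q - (a + t * ab))^2))
}
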