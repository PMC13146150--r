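# Synthetic minority oversampling: convex interpolation between a minority
# point and one of its k nearest minority neighbours, up to exact class
# balance. Applied to training partitions only.

#' Oversample the minority class to exact balance (SMOTE)
#'
#' Synthetic minority rows are drawn as `x_s + gap * (x_nb - x_s)` with
#' `gap ~ U(0, 1)`, where `x_nb` is one of the `k` nearest minority
#' neighbours of the seed point `x_s` (Euclidean distance in feature space).
#' When the minority class is larger than `candidate_pool`, the neighbour
#' search runs against a seeded random subsample of that size, keeping cost
#' linear in the minority count; below the cap the search is exact.
#'
#' @param x numeric feature matrix.
#' @param y binary outcome vector (two classes required).
#' @param k neighbourhood size (>= 1); reduced with a warning if it reaches
#'   the minority count.
#' @param seed integer seed for neighbour choice and interpolation weights.
#' @param candidate_pool cap on the neighbour-search reference set.
#' @return list with balanced `x`, `y` and `n_synthetic`.
#' @export
oversample_minority <- function(x, y, k = 5L, seed = 1L, candidate_pool = 600L) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = sort(unique(y))))
  if (length(tab) < 2L) stop_config("oversampling needs both classes present")
  if (k < 1L) stop_config("oversample_k must be >= 1")
  minority <- as.integer(names(tab)[which.min(tab)])
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min == n_maj)
    return(list(x = x, y = y, n_synthetic = 0L))
  if (k >= n_min) {
    k <- max(1L, n_min - 1L)
    warning(sprintf("k reduced to %d (minority count %d)", k, n_min))
  }
  idx_min <- which(y == minority)
  xm <- x[idx_min, , drop = FALSE]
  n_needed <- n_maj - n_min

  with_seed(seed, {
    if (nrow(xm) < 2L) {
      syn <- xm[rep(1L, n_needed), , drop = FALSE]
    } else {
      pool_idx <- if (nrow(xm) > candidate_pool)
        sample.int(nrow(xm), candidate_pool) else seq_len(nrow(xm))
      pool <- xm[pool_idx, , drop = FALSE]
      nb <- knn_index(xm, pool, pool_idx, k)
      seed_i <- sample.int(nrow(xm), n_needed, replace = TRUE)
      pick <- nb[cbind(seed_i, sample.int(ncol(nb), n_needed, replace = TRUE))]
      gap <- stats::runif(n_needed)
      syn <- xm[seed_i, , drop = FALSE] +
        gap * (xm[pick, , drop = FALSE] - xm[seed_i, , drop = FALSE])
    }
    list(x = rbind(x, syn),
         y = c(y, rep.int(minority, n_needed)),
         n_synthetic = n_needed)
  })
}

# k-nearest-neighbour indices (into the full minority set) for every minority
# row, searched within `pool` (rows pool_idx of the minority set). Chunked
# squared-distance computation via BLAS; a point is never its own neighbour.
knn_index <- function(xm, pool, pool_idx, k) {
  n <- nrow(xm)
  k <- min(k, nrow(pool) - 1L)
  if (k < 1L) k <- 1L
  pn2 <- rowSums(pool^2)
  out <- matrix(0L, n, k)
  chunk <- max(1L, floor(4e6 / nrow(pool)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    xs <- xm[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xs^2), pn2, "+") - 2 * tcrossprod(xs, pool)
    # mask self-matches for rows that are in the pool
    self <- match(s:e, pool_idx)
    hit <- !is.na(self)
    if (any(hit)) d2[cbind(which(hit), self[hit])] <- Inf
    for (j in seq_len(k)) {
      nn <- max.col(-d2, ties.method = "first")
      out[s:e, j] <- pool_idx[nn]
      d2[cbind(seq_len(nrow(d2)), nn)] <- Inf
    }
  }
  out
}
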