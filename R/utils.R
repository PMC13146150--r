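# Internal helpers shared across modules.

# data.table is used via explicit data.table:: calls
.datatable.aware <- TRUE

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' `.Random.seed`, so seeded internals never perturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a label, staying below 2^31.
# Deterministic and label-sensitive so e.g. every retrain date gets its own
# reproducible stream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

logit <- function(p) log(p / (1 - p))

inv_logit <- stats::plogis

# Clip probabilities away from {0, 1} before logit transforms.
clip_prob <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
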