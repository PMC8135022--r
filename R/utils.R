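# Small internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_rng_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# 0-based half-open character span -> substring of `text`; vectorized over
# start/end.
substr0 <- function(text, start, end) substring(text, start + 1L, end)

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column-wise log-sum-exp of a matrix.
col_log_sum_exp <- function(m) {
  mx <- apply(m, 2L, max)
  mx + log(colSums(exp(sweep(m, 2L, mx, "-"))))
}

empty_entities <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), surface = character(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), type = character(), attr_id = character(),
             drug_id = character(), stringsAsFactors = FALSE)
}

f1_score <- function(p, r) if ((p + r) == 0) 0 else 2 * p * r / (p + r)

prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = p, recall = r, f1 = f1_score(p, r))
}
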