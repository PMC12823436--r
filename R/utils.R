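# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a stage label
#'
#' One master seed fans out to per-stage seeds through a small deterministic
#' hash of the label, so that stages draw from independent streams and adding
#' a stage never perturbs another stage's randomness.
#'
#' @param master integer master seed.
#' @param label character stage label (e.g. `"mediation"`, or a triple id).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer((abs(master) + h) %% 2147483647)
}

# run an expression under a local RNG state with the given seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# assert a single positive integer-ish scalar
check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %s, got %s",
                  name, min, deparse(x)))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must lie in %s%s, %s%s; got %s", name,
                  if (lo_open) "(" else "[", lo, hi,
                  if (hi_open) ")" else "]", deparse(x)))
  }
  as.numeric(x)
}

# Stratified fold assignment on deciles of a numeric target: stabilises
# per-fold R^2 for skewed targets. Returns an integer vector in 1..k.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  with_seed(seed, {
    bins <- cut(rank(y, ties.method = "first"),
                breaks = min(10L, max(2L, n %/% k)),
                labels = FALSE)
    fold <- integer(n)
    for (b in unique(bins)) {
      idx <- which(bins == b)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# holdout R^2 with the held-out fold's own mean in the denominator
holdout_r2 <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}
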