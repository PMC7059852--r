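# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# Restores the caller's .Random.seed afterwards so seeded package
# functions do not perturb the user's random stream. seed = NULL means
# "use the current stream" (and do not restore).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, so that e.g. the
# (depth, replicate) grid of a subsampling experiment is reproducible
# cell by cell. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  base <- as.double(as.integer(seed)) %% 2147483647
  as.list(as.integer((base + 7919 * seq_len(n)) %% 2147483647))
}

# One multivariate hypergeometric draw: `k` items taken without
# replacement from categories with sizes `counts`. Sequential
# conditional rhyper() draws, O(#categories) regardless of depth.
rmvhyper1 <- function(counts, k) {
  counts <- as.double(counts)
  stopifnot(all(counts >= 0), k >= 0, k <= sum(counts))
  out <- numeric(length(counts))
  remaining <- sum(counts)
  for (i in seq_along(counts)) {
    if (k <= 0) break
    ci <- counts[i]
    remaining <- remaining - ci
    x <- stats::rhyper(1L, ci, remaining, k)
    out[i] <- x
    k <- k - x
  }
  out
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    abs(x - round(x)) < 1e-8
}

`%||%` <- function(a, b) if (is.null(a)) b else a
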