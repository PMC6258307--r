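#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## row-wise log-sum-exp of a matrix
row_logsumexp <- function(A) {
  m <- as.numeric(apply(A, 1L, max))
  out <- m + log(rowSums(exp(A - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## All randomness in the package flows through explicit seeds via this helper;
## no function perturbs the global RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-stream seeds: one master seed fans out to numbered
## streams (starts, replicates) while staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
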