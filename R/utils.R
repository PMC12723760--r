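# Internal numerical helpers shared across modules.

# Row-wise log-sum-exp of a matrix; returns vector of length nrow(m).
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Derive a child RNG seed from a base seed and a stream index.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 1103515245 * as.double(stream)) %% 2147483629L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
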