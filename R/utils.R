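# internal helpers shared across modules

# Evaluate `expr` under a locally seeded RNG when `seed` is non-NULL,
# leaving the caller's RNG stream untouched; otherwise use the current stream.
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive a bounded child seed from a base seed and a stream index.
# Kept below 2^31 - 1 (R integers are 32-bit).
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(stream) * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

off_diag <- function(m) m[row(m) != col(m)]
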