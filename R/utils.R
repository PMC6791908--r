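# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    rlang::abort("`seed` must be a single integer.")
  }
  withr::with_seed(as.integer(seed), code)
}

# Derive a child seed from a parent seed and a stream index, staying < 2^31.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %% 2147483587)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    rlang::abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                         format(lower), format(upper)))
  }
  invisible(x)
}
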