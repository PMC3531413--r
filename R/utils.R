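# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  `seed = NULL` means: use the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a child seed from a base seed and an index,
# keeping the result in the 32-bit signed integer range.
derive_seed <- function(base, index) {
  as.integer((as.double(base) * 48271 + index * 9973) %% 2147483587L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
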