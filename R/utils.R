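# Internal utilities.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a base seed and integer tags,
# staying within the 32-bit integer range.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483647
  for (t in tags) x <- (x * 48271 + as.double(t)) %% 2147483647
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
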