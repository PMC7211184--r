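# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_invalid("'%s' must be > 0", name)
  if (nonneg && x < 0) stop_invalid("'%s' must be >= 0", name)
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# the caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 9973) %% 2147483563) + 1L
}
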