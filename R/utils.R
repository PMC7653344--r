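# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
# `seed` may be NULL (no seeding; caller's stream is used and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Derive a child seed from a parent seed and a stream label, staying well
# below .Machine$integer.max so downstream set.seed() calls are valid.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  # double arithmetic: intermediate stays below 2^53, result below 2^31
  as.integer((as.numeric(seed) %% 2147483 * 1000003 +
                as.numeric(stream)) %% 2147483)
}

stop_fe <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_fe("'%s' must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_fe("'%s' must be > %g (got %g)", name, lower, x)
  }
  if (!strict_lower && x < lower) {
    stop_fe("'%s' must be >= %g (got %g)", name, lower, x)
  }
  if (x > upper) stop_fe("'%s' must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
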