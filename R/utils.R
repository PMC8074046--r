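# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`.
# `seed = NULL` uses (and advances) the global RNG stream, so callers can
# still obtain reproducibility with an outer set.seed().
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Validation helper: stop with a message naming the offending field.
assert_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  invisible(TRUE)
}

assert_positive <- function(x, field) {
  assert_that(is.numeric(x) && all(is.finite(x)) && all(x > 0),
              field, "must be a finite positive number")
}

assert_nonnegative <- function(x, field) {
  assert_that(is.numeric(x) && all(is.finite(x)) && all(x >= 0),
              field, "must be a finite non-negative number")
}

assert_probability <- function(x, field) {
  assert_that(is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1),
              field, "must lie in [0, 1]")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
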