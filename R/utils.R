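# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. All stochastic routines in the package go
# through this, so no function mutates global RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# stopifnot() with a formatted message
check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

is_count_vector <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(abs(x - round(x)) <= tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
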