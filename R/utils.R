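#' @keywords internal
"_PACKAGE"

# Run `expr` under a private RNG stream started from `seed`, restoring the
# caller's .Random.seed afterwards.  Every stochastic operation in the
# package routes through this so no call mutates global RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Derive a child seed from a master seed; keeps all child seeds < 2^31.
child_seed <- function(seed, offset) {
  (as.integer(seed) * 1103L + as.integer(offset) * 7919L) %% 2147483587L
}

stop_ldsig <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
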