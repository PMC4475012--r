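# internal helpers shared across modules

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# bit j (1-based) of non-negative integer code vector
bit_of <- function(code, j) bitwAnd(bitwShiftR(code, j - 1L), 1L)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort2 <- function(...) stop(..., call. = FALSE)
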