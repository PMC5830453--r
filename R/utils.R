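#' Evaluate an expression under a fixed RNG seed
#'
#' Sets the RNG seed, runs `expr`, and restores the caller's RNG state on
#' exit, so that seeded package operations never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
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

#' Derive a sub-stream seed from a base seed
#'
#' Deterministic mixing of a base seed and an index, kept within the 32-bit
#' signed integer range so the result is always a valid `set.seed()` argument.
#'
#' @param base Integer base seed.
#' @param i Non-negative integer index.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base, i) {
  as.integer((as.double(base) * 48271 + as.double(i) * 69621) %% 2147483647)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
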