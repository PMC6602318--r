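## internal assertion / misc helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(name, " must be a single finite number")
  if (positive && x <= 0) stop2(name, " must be > 0")
  if (nonneg && x < 0) stop2(name, " must be >= 0")
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, runs `expr`, and restores the caller's RNG state, so
#' seeded internals (e.g. Monte Carlo Dunnett) never perturb user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

## derive a per-stream 31-bit seed from (seed, id); keeps values < 2^31
derive_seed <- function(seed, id) {
  as.integer((as.double(seed) * 2654435761 + as.double(id) * 40503 + 12345) %%
               2147483647)
}
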