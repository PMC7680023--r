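#' Evaluate an expression with a private RNG state
#'
#' Runs `expr` after seeding the RNG with `seed`, then restores the caller's
#' RNG state, so seeded operations never perturb the global random stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting so independent stages of a pipeline can be seeded
#' from one user-facing integer. Result is kept within 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param k stage index (small positive integer).
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 2654435761) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_holopop <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
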