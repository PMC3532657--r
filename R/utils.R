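#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local, restorable RNG state
#'
#' All generators route their randomness through this helper so that a given
#' (spec, seed) pair is bit-reproducible and never disturbs the caller's RNG.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# derive a child seed < 2^31 from a parent seed and a stream index
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0
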