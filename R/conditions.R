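# Structured error conditions used across the package. Each abort() call
# raises a classed condition so callers (and tests) can match on failure
# kind rather than message text.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hepatens_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state so
#' seeded internals never perturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a distinct child seed from a master seed; kept below 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647
}
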