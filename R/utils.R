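# internal helpers

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' random-number state, so seeded generators are pure functions of their
#' arguments and never perturb user code.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a parent seed and a stream index, kept < 2^31
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483647)
}

# truncate (not round) x to two decimals, the convention of the printed
# energy-expenditure tables
trunc2 <- function(x) trunc(x * 100) / 100

stopifnot_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name))
  if (strict && x <= min) stop(sprintf("'%s' must be > %g", name, min))
  if (!strict && x < min) stop(sprintf("'%s' must be >= %g", name, min))
  invisible(x)
}
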