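#' Evaluate an expression under a local random seed
#'
#' All stochastic operations in wheatSeg draw their randomness through this
#' helper: the global RNG state is saved, a private stream is seeded, and the
#' global state is restored afterwards, so package calls never perturb (nor
#' depend on) the caller's RNG.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

## Derive a child seed from a parent seed and a stream index, staying well
## inside 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629) + 1L
}

#' Undefined metric marker
#'
#' Metrics with a zero denominator are undefined rather than zero; wheatSeg
#' represents them as `NA_real_` and excludes them from averages with a
#' warning. `isUndefined()` tests for the marker.
#'
#' @param x numeric vector.
#' @return logical vector.
#' @export
isUndefined <- function(x) is.na(x)

undefinedValue <- function() NA_real_

## assert helpers -----------------------------------------------------------

assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

assertCount <- function(x, name) {
  assertScalarNumber(x, name, lower = 0)
  if (x != round(x))
    stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
  invisible(as.integer(x))
}

assertMask <- function(mask, name = "mask") {
  if (!is.matrix(mask))
    stop(sprintf("'%s' must be a matrix", name), call. = FALSE)
  if (!all(mask %in% c(0L, 1L, 2L)))
    stop(sprintf("'%s' must contain only labels 0, 1, 2", name), call. = FALSE)
  invisible(mask)
}
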