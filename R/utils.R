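# Internal helpers: argument checking and reproducible seed streams.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("`%s` must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package fans out from one root seed through this
#' splitter, so that (for example) adding a participant to a simulated cohort
#' does not perturb the trials of existing participants. The stream index is
#' hashed onto 31-bit integers with a multiplicative congruential step.
#'
#' @param seed root integer seed.
#' @param ... one or more non-negative integer stream indices (participant,
#'   condition, trial, stage, ...).
#' @return a single integer usable with [set.seed()].
#' @export
sub_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (k in idx) {
    # 48271 = MINSTD multiplier; keeps everything inside 31 bits
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
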