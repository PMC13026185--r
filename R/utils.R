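#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the previous
#' RNG state, so that seeded helpers never perturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to run unseeded.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a parent seed
#'
#' Stages of the pipeline draw from child seeds at fixed offsets so each stage
#' is individually reproducible. Values are kept below 2^31 - 1.
#'
#' @param seed Parent integer seed.
#' @param offset Stage offset (small integer).
#' @return An integer seed.
#' @keywords internal
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset * 9973) %% 2147483587L)
}

stop_if <- function(cond, ...) {
  if (cond) stop(sprintf(...), call. = FALSE)
}

is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0 & x <= 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean and standard error of a numeric vector
#' @param x Numeric vector (NAs dropped).
#' @return Named vector with `mean` and `se` (sd/sqrt(n)).
#' @keywords internal
mean_se <- function(x) {
  x <- x[!is.na(x)]
  c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)))
}
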