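#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a master seed and an index
#'
#' A Lehmer-style mix keeping every intermediate below 2^53 so the arithmetic
#' is exact in doubles, and the result below 2^31 so it is a valid R seed.
#' @noRd
mix_seed <- function(seed, k) {
  x <- as.numeric(seed) %% 2147483647
  x <- (x * 48271 + as.numeric(k) * 7919 + 12345) %% 2147483647
  as.integer(x)
}

#' Set the RNG only when a seed is supplied
#' @noRd
maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Truncated-normal draws via inverse-CDF sampling
#' @noRd
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' @noRd
stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_bad("`%s` must be a probability in [0, 1], got %s", name,
             paste(format(x), collapse = ", "))
  invisible(x)
}

#' @noRd
assert_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || anyNA(x) || x[1] > x[2])
    stop_bad("`%s` must be an ordered numeric interval c(lo, hi)", name)
  invisible(x)
}
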