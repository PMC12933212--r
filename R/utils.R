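#' Derive an independent random-number substream seed
#'
#' Analyses that mix several sources of randomness (lesion simulation,
#' permutation tests, bootstrap resampling) derive one integer seed per stream
#' from a single master seed, so that streams do not overlap and adding
#' subjects or iterations to one stream never reshuffles another.
#'
#' Uses one step of the Lehmer multiplicative congruential map modulo the
#' Mersenne prime 2^31 - 1 applied to `master_seed + stream`; all intermediate
#' products stay below 2^53 so the arithmetic is exact in doubles.
#'
#' @param master_seed Integer master seed.
#' @param stream Non-negative integer stream identifier.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
#' @export
derive_seed <- function(master_seed, stream = 0L) {
  m <- 2147483647
  x <- (abs(as.numeric(master_seed)) + as.numeric(stream)) %% m
  s <- (x * 48271) %% m
  if (s == 0) s <- 1
  as.integer(s)
}

# shared add-one permutation p estimator
perm_pvalue <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

`%||%` <- function(a, b) if (is.null(a)) b else a
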