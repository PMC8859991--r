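#' @importFrom stats rbeta rnorm rexp runif median setNames complete.cases
#' @importFrom utils head
NULL

# round half up (away from zero for positive x); base round() is banker's
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Percentage helper used across summary tables
#'
#' Computes `100 * count / total` rounded half-up to two decimals, the
#' convention used for all printed percentages in this package.
#'
#' @param count numerator count(s)
#' @param total denominator
#' @param digits decimal places (default 2)
#' @return numeric vector of percentages
#' @export
percent_of <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, digits)
}

# derive a reproducible sub-seed (< 2^31) from a base seed and a stage tag
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + offs) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
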