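#' @import stats
#' @importFrom utils modifyList read.table write.table
#' @importFrom methods is
NULL

#' Derive a deterministic substream seed
#'
#' All randomness in the package flows from one integer seed; independent
#' stages draw from substreams derived by hashing a stage label into the
#' master seed. Keeps every derived seed a valid 32-bit integer.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Percentage of a count over a total, rounded for reporting
#'
#' Reporting helper used throughout summary tables: percentages are printed
#' as 100 * x / n rounded to a fixed number of decimals.
#'
#' @param x numerator count.
#' @param n denominator count.
#' @param digits decimals to keep (default 1).
#' @return rounded percentage.
#' @export
percent_of <- function(x, n, digits = 1) {
  stopifnot(n > 0)
  round(100 * x / n, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
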