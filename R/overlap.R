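#' Linear-interpolation percentile
#'
#' The q-th percentile of a sample under the linear interpolation convention
#' (q = 0 gives the minimum, q = 100 the maximum). This is the percentile
#' definition underlying the distribution-overlap statistic.
#'
#' @details
#' Computed directly from the sorted order statistics as
#' `x[lo] + (h - lo) * (x[hi] - x[lo])` with `h = (n - 1) q / 100`,
#' the canonical linear-interpolation definition (equal to
#' `stats::quantile(type = 7)` up to floating-point rounding; the direct form
#' keeps exact ties exact, which the overlap scan's `>=` comparison relies
#' on).
#'
#' @param x Non-empty numeric sample (missing values are dropped).
#' @param q Percentage(s) in `[0, 100]`.
#' @return Percentile value(s).
#' @export
percentile <- function(x, q) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("no measurements")
  if (any(q < 0 | q > 100)) stop("q must be in [0, 100]")
  x <- sort(x)
  h <- (length(x) - 1) * q / 100
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo + 1] + (h - lo) * (x[hi + 1] - x[lo + 1])
}

#' Percentile-based overlap between two distributions
#'
#' Computes the overlap percentage delta between two samples A and B under
#' the assumption that values of B are generally greater than those of A when
#' the muscle is contracted. The statistic seeks the smallest alpha on the
#' integer grid 0..100 such that the alpha-th percentile of A is at least the
#' (100 - alpha)-th percentile of B, and returns `delta = 100 - alpha_hat`.
#'
#' Fully separated samples with B above A give 0; B entirely below A gives
#' 100; identical samples with at least two distinct values give 50. If no
#' grid alpha satisfies the condition (A entirely below B even at the
#' extremes), alpha_hat is 100 and delta is 0, by continuity with the
#' just-touching case.
#'
#' The search exploits that the condition is monotone in alpha (binary
#' search); it is exactly equivalent to a full scan over all 101 grid values.
#'
#' @param a,b Non-empty numeric samples (missing values are dropped).
#' @return Overlap percentage in `[0, 100]` (integer-valued).
#' @export
distribution_overlap <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("no measurements")
  cond <- function(alpha) percentile(a, alpha) >= percentile(b, 100 - alpha)
  if (!cond(100)) return(0)   # condition never met on the grid
  if (cond(0)) return(100)
  lo <- 0L; hi <- 100L        # invariant: !cond(lo), cond(hi)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (cond(mid)) hi <- mid else lo <- mid
  }
  100 - hi
}
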