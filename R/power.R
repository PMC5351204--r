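# Two-sample, unequal-n t-test power from the noncentral t distribution, and
# the minimum detectable methylation difference it implies.

#' Power of a two-sample t test with unequal group sizes
#'
#' `power = P(|T'| > t_crit)` where `T'` is noncentral t with
#' `df = n1 + n2 - 2` and noncentrality `d * sqrt(n1 * n2 / (n1 + n2))`, and
#' `t_crit` is the two-sided `alpha` critical value.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param d Cohen's d effect size.
#' @param alpha significance level (default 0.05).
#' @return power in (0, 1).
#' @export
t2n_power <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' Minimum detectable methylation difference
#'
#' Solves [t2n_power()] for Cohen's d by bisection (to 1e-6) at the target
#' power, then scales by the per-site standard deviation to express the
#' answer in percentage points. The SD is a required input: it is a property
#' of the data at hand, not of the test.
#'
#' @param n1,n2 group sizes.
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.80).
#' @param sd per-site methylation standard deviation (percentage points).
#' @return list with `d` (Cohen's d) and `diff` (`d * sd`, percentage
#'   points).
#' @export
min_detectable_diff <- function(n1, n2, alpha = 0.05, power = 0.80, sd) {
  stopifnot(sd > 0, power > alpha, power < 1)
  lo <- 1e-8; hi <- 1
  while (t2n_power(n1, n2, hi, alpha) < power) {
    hi <- hi * 2
    if (hi > 100) stop("power target not bracketed")
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (t2n_power(n1, n2, mid, alpha) < power) lo <- mid else hi <- mid
  }
  d <- (lo + hi) / 2
  list(d = d, diff = d * sd)
}
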