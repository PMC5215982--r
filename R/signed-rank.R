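#' Null moments of the signed-rank statistic
#'
#' Mean and variance of the one-sample signed-rank statistic (sum of ranks
#' of positive deviations) under the null hypothesis of symmetry about the
#' test center: mean n(n+1)/4 and variance n(n+1)(2n+1)/24.
#'
#' @param n Number of non-zero deviations (>= 1).
#' @return Named numeric vector with elements `mean` and `variance`.
#' @export
null_moments <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  c(mean = n * (n + 1) / 4, variance = n * (n + 1) * (2 * n + 1) / 24)
}

#' Moment of the k-th order-statistic sign indicator
#'
#' Expectation of the Bernoulli indicator that the deviation holding
#' absolute rank k is positive, for a continuous distribution symmetric
#' about the center: `(n/2) * choose(n-1, k-1) * B(k, n-k+1)`, which
#' simplifies to 1/2 for every k. Provided as a documented helper; the
#' hypothesis tests use the simplified null moments directly.
#'
#' @param k Rank (1..n).
#' @param n Sample size.
#' @return The expectation (numerically 1/2).
#' @export
order_indicator_moment <- function(k, n) {
  stopifnot(k >= 1, k <= n)
  n / 2 * choose(n - 1, k - 1) * beta(k, n - k + 1)
}

#' One-sided signed-rank test with normal approximation
#'
#' Tests whether `values` tend to exceed `center`. Deviations equal to zero
#' are dropped; absolute deviations are ranked ascending with midranks for
#' ties; the statistic is the sum of the ranks carrying a positive sign.
#' The p-value is the upper tail of the normal approximation with the null
#' moments at the effective sample size; no continuity correction is
#' applied.
#'
#' @param values Numeric vector.
#' @param center Null center of symmetry.
#' @return List with `t_plus`, `z`, `p_value` and `n_effective`.
#' @export
signed_rank_test <- function(values, center) {
  r <- values - center
  r <- r[r != 0]
  n <- length(r)
  if (n == 0L) stop("degenerate: no nonzero deviations")
  rk <- rank(abs(r))
  t_plus <- sum(rk[r > 0])
  mom <- null_moments(n)
  z <- (t_plus - mom[["mean"]]) / sqrt(mom[["variance"]])
  list(t_plus = t_plus, z = z,
       p_value = stats::pnorm(z, lower.tail = FALSE), n_effective = n)
}

#' Exact one-sided signed-rank p-value by sign enumeration
#'
#' Enumerates all 2^n sign assignments of the absolute deviations and
#' returns the exact probability of a statistic at least as large as the
#' observed one under the null of symmetry. Intended as a reference for the
#' normal approximation at small n.
#'
#' @inheritParams signed_rank_test
#' @return List with `t_plus` and exact `p_value`.
#' @export
signed_rank_exact <- function(values, center) {
  r <- values - center
  r <- r[r != 0]
  n <- length(r)
  if (n == 0L) stop("degenerate: no nonzero deviations")
  if (n > 20L) stop("exact enumeration limited to n <= 20")
  rk <- rank(abs(r))
  obs <- sum(rk[r > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats_all <- as.vector(signs %*% rk)
  list(t_plus = obs, p_value = mean(stats_all >= obs))
}
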