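# Non-parametric inference: BCa intervals, permutation tests of zero
# correlation, and the Hettmansperger-Norton patterned-trend test.

# norm-interpolated order statistic at probability p (the standard
# adjusted-percentile convention for bootstrap intervals): interpolate
# between order statistics k and k+1, k = floor((B+1) p), on the
# normal-quantile scale.
norm_interp_quantile <- function(sorted, p) {
  B <- length(sorted)
  k <- (B + 1) * p
  lo <- floor(k)
  if (lo < 1) return(sorted[1])
  if (lo >= B) return(sorted[B])
  frac <- (qnorm(p) - qnorm(lo / (B + 1))) /
    (qnorm((lo + 1) / (B + 1)) - qnorm(lo / (B + 1)))
  sorted[lo] + frac * (sorted[lo + 1] - sorted[lo])
}

#' Bias-corrected and accelerated (BCa) bootstrap confidence interval
#'
#' The bias correction is `z0 = qnorm(#\{boot < theta_hat\} / B)` with the
#' count clamped to \[1, B-1\]; the acceleration is the jackknife skewness
#' `a = sum((m - j_i)^3) / (6 * sum((m - j_i)^2)^(3/2))` with `m` the
#' jackknife mean. Interval endpoints are adjusted-percentile order
#' statistics of the bootstrap values (normal-scale interpolation).
#'
#' @param theta_hat Statistic on the original data.
#' @param boot_values Bootstrap replicate values (length `B >= 100`).
#' @param jackknife_values Leave-one-out statistic values (length `n >= 3`).
#' @param level Coverage (default 0.95).
#' @return Object of class `bca_interval`: list with `lower`, `upper`,
#'   `level`, `z0`, `a`.
#' @export
bca_interval <- function(theta_hat, boot_values, jackknife_values,
                         level = 0.95) {
  B <- length(boot_values)
  if (B < 100L) bt_stop("need at least 100 bootstrap values", "barotrend_param_error")
  if (length(jackknife_values) < 3L) {
    bt_stop("need at least 3 jackknife values", "barotrend_param_error")
  }
  if (diff(range(boot_values)) == 0) {
    bt_stop("constant bootstrap distribution: BCa undefined",
            "barotrend_degenerate_error")
  }
  cnt <- sum(boot_values < theta_hat)
  cnt <- min(max(cnt, 1L), B - 1L)
  z0 <- qnorm(cnt / B)
  d <- mean(jackknife_values) - jackknife_values
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)
  zq <- qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  s <- sort.int(boot_values, method = "quick")
  structure(list(lower = norm_interp_quantile(s, adj[1]),
                 upper = norm_interp_quantile(s, adj[2]),
                 level = level, z0 = z0, a = a),
            class = "bca_interval")
}

#' Leave-one-out Winsorized correlations
#'
#' Jackknife values of `wincorr` for use as the acceleration input of
#' [bca_interval()].
#'
#' @param x,y Numeric vectors of equal length.
#' @param gamma Winsorizing proportion.
#' @return Numeric vector of length `n`.
#' @export
jackknife_wincorr <- function(x, y, gamma = 0.1) {
  n <- length(x)
  vapply(seq_len(n), function(i) wincorr(x[-i], y[-i], gamma), numeric(1))
}

#' Permutation test of zero Winsorized correlation
#'
#' The observed statistic is `wincorr(x, y, gamma)`; under the null of zero
#' correlation the pairing is exchangeable, so `y` is permuted uniformly
#' `n_perm` times and the two-sided p-value is
#' `(1 + #\{|T*| >= |T|\}) / (n_perm + 1)`. Winsorization commutes with
#' permutation (the clamping thresholds depend only on the multiset of
#' values), so both vectors are winsorized and standardized once and each
#' permutation reduces to an inner product.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param gamma Winsorizing proportion (default 0.1).
#' @param n_perm Number of permutations (default 5000).
#' @param seed RNG seed.
#' @return Object of class `permutation_result`: list with `observed`,
#'   `p_value`, `n_perm`.
#' @export
permutation_test_corr <- function(x, y, gamma = 0.1, n_perm = 5000, seed = 1L) {
  t_obs <- wincorr(x, y, gamma)  # validates inputs, errors on degeneracy
  n <- length(x)
  zx <- scale(winsorize(x, gamma))[, 1]
  zy <- scale(winsorize(y, gamma))[, 1]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  denom <- n - 1
  t_abs <- abs(t_obs)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    t_star <- sum(zx * zy[sample.int(n)]) / denom
    if (abs(t_star) >= t_abs - 1e-12) hits <- hits + 1L
  }
  structure(list(observed = t_obs,
                 p_value = (1 + hits) / (n_perm + 1),
                 n_perm = n_perm),
            class = "permutation_result")
}

#' Patterned-trend score vectors over the ordered SAP groups
#'
#' Canonical scores for the four alternatives on (Nt, preHt, Ht):
#' increasing (1,2,3), decreasing (3,2,1), concave / umbrella peak in the
#' middle (1,2,1), convex / umbrella trough in the middle (2,1,2).
#'
#' @return Named list of numeric score vectors of length 3.
#' @export
trend_scores <- function() {
  list(increasing = c(1, 2, 3),
       decreasing = c(3, 2, 1),
       concave    = c(1, 2, 1),
       convex     = c(2, 1, 2))
}

#' Hettmansperger-Norton test against a patterned alternative
#'
#' Pools all `N` values, assigns midranks, centers the pattern scores `q_i`
#' to `c_i = q_i - sum(n_j q_j) / N` (so `sum(n_i c_i) = 0`), and forms
#' `T = sum(c_i * Rbar_i)` with `Rbar_i` the group mean rank, centered at
#' its null mean `Rbar * sum(c_i)` (zero for equal group sizes). The null
#' variance is the exact permutation variance of this linear rank
#' statistic, `Var(T) = sigma_R^2 * N/(N-1) * (sum(c_i^2 / n_i) -
#' (sum(c_i))^2 / N)` with `sigma_R^2` the population variance of the
#' pooled midranks (the second term vanishes for equal group sizes), giving
#' `z = T / sqrt(Var(T))` and an upper-tail normal p-value. With equal
#' group sizes (as when applied to the three within-group bootstrap
#' distributions, each of size B) pseudoranks coincide with plain ranks.
#'
#' @param samples List of 3 numeric vectors in group order (Nt, preHt, Ht),
#'   each of length >= 2.
#' @param scores Numeric score vector of length 3 (see [trend_scores()]),
#'   not constant.
#' @return List with `z`, `p_value`, `statistic` (the centered `T`).
#' @export
hn_trend_test <- function(samples, scores) {
  if (length(samples) != 3L || length(scores) != 3L) {
    bt_stop("need 3 samples and 3 scores", "barotrend_param_error")
  }
  if (diff(range(scores)) == 0) {
    bt_stop("scores must not be constant", "barotrend_param_error")
  }
  n <- lengths(samples)
  if (any(n < 2L)) bt_stop("each sample needs >= 2 values", "barotrend_param_error")
  N <- sum(n)
  R <- rank(unlist(samples, use.names = FALSE))
  sigma2 <- mean((R - mean(R))^2)
  if (sigma2 == 0) bt_stop("all values tied: trend test undefined",
                           "barotrend_degenerate_error")
  grp <- rep(seq_len(3L), n)
  rbar <- tapply(R, grp, mean)
  cc <- scores - sum(n * scores) / N
  T_stat <- sum(cc * rbar) - mean(R) * sum(cc)  # centered at its null mean
  varT <- sigma2 * N / (N - 1) * (sum(cc^2 / n) - sum(cc)^2 / N)
  z <- T_stat / sqrt(varT)
  list(z = z, p_value = pnorm(z, lower.tail = FALSE), statistic = T_stat)
}
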