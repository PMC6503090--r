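test_that("BCa reduces to the percentile interval when z0 = a = 0", {
  set.seed(55)
  boot_v <- rnorm(4000)
  boot_v <- c(boot_v, -boot_v)  # exactly symmetric around 0
  theta <- 0                    # at the median: z0 = 0
  jack <- seq(-5, 5, length.out = 21)  # symmetric: a = 0
  ci <- bca_interval(theta, boot_v, jack, level = 0.95)
  expect_equal(ci$z0, 0)
  expect_equal(ci$a, 0)
  expect_equal(ci$lower, quantile(boot_v, 0.025, names = FALSE),
               tolerance = 0.01)
  expect_equal(ci$upper, quantile(boot_v, 0.975, names = FALSE),
               tolerance = 0.01)
  expect_lte(ci$lower, ci$upper)
})

test_that("constant bootstrap distribution raises an error", {
  expect_error(bca_interval(0.5, rep(0.5, 500), rnorm(10)),
               class = "barotrend_degenerate_error")
  expect_error(bca_interval(0.5, rnorm(50), rnorm(10)),
               class = "barotrend_param_error")
})

test_that("BCa endpoints match the reference implementation in boot", {
  set.seed(77)
  dat <- rnorm(20, mean = 1, sd = 1.5)
  bo <- boot::boot(dat, function(d, i) mean(d[i]), R = 2000)
  ref <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(dat), function(i) mean(dat[-i]), numeric(1))
  ci <- bca_interval(mean(dat), as.vector(bo$t), jack)
  expect_equal(ci$lower, ref[1], tolerance = 0.005)
  expect_equal(ci$upper, ref[2], tolerance = 0.005)
})

test_that("permutation p attains its lower bound for a perfect correlation", {
  x <- rnorm(20)
  res <- permutation_test_corr(x, x, gamma = 0.1, n_perm = 999, seed = 31)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$observed, 1)
  # p can never undercut 1 / (n_perm + 1)
  set.seed(8)
  for (i in 1:5) {
    r <- permutation_test_corr(rnorm(15), rnorm(15), 0.1, n_perm = 99,
                               seed = i)
    expect_gte(r$p_value, 1 / 100)
    expect_lte(r$p_value, 1)
  }
})

test_that("Monte-Carlo permutation p matches exact enumeration at n = 4", {
  x <- c(0.3, -1.2, 0.8, 2.1)
  y <- c(1.0, -0.4, 0.1, 1.3)
  r_obs <- abs(cor(x, y))
  perms <- all_perms(4L)
  r_all <- apply(perms, 1, function(p) abs(cor(x, y[p])))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  res <- permutation_test_corr(x, y, gamma = 0, n_perm = 4800, seed = 12)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 4800) + 1 / 4800
  expect_lt(abs(res$p_value - p_exact), tol)
})

test_that("HN z equals the exact enumeration standardization on the fixture", {
  samples <- list(c(1, 2), c(5, 6), c(3, 4))
  for (nm in names(trend_scores())) {
    q <- trend_scores()[[nm]]
    z_exact <- hn_exact_z(samples, q)
    expect_equal(hn_trend_test(samples, q)$z, z_exact, tolerance = 1e-10)
  }
  # number of equal-size allocations of 6 items into three pairs is 90
  expect_equal(length(all_allocations(c(2L, 2L, 2L))), 90L)
})

test_that("HN test is consistent in the pattern direction", {
  set.seed(3)
  lo <- rnorm(40)
  hi <- rnorm(40) + 5
  res <- hn_trend_test(list(lo, hi, rnorm(40)), trend_scores()$concave)
  expect_gt(res$z, 3)
  expect_lt(res$p_value, 0.001)
  # inverted pattern: convex scores on the same data go the other way
  expect_lt(hn_trend_test(list(lo, hi, rnorm(40)),
                          trend_scores()$convex)$z, 0)
  expect_error(hn_trend_test(list(rep(1, 5), rep(1, 5), rep(1, 5)),
                             trend_scores()$concave),
               class = "barotrend_degenerate_error")
  expect_error(hn_trend_test(list(lo, hi), c(1, 2)),
               class = "barotrend_param_error")
})

test_that("HN rejection rate is near nominal under the null", {
  set.seed(17)
  rej <- 0L
  nsim <- 1000
  for (i in seq_len(nsim)) {
    s <- list(rnorm(30), rnorm(30), rnorm(30))
    if (hn_trend_test(s, trend_scores()$concave)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / nsim, 0.03)
  expect_lt(rej / nsim, 0.07)
})

test_that("trend classification follows medians, permutation and HN verdicts", {
  groups <- sap_groups()
  med <- matrix(0.52, 1, 4, dimnames = list("ansi", analysis_scopes()))
  med[1, groups] <- c(0.5, 0.618, 0.444)
  perm_p <- matrix(0.001, 1, 4, dimnames = dimnames(med))
  hn_sig <- function(z, p) list(z = z, p_value = p)
  hn <- list(ansi = list(increasing = hn_sig(-1, 0.8),
                         decreasing = hn_sig(1, 0.2),
                         concave = hn_sig(9, 1e-9),
                         convex = hn_sig(-9, 1)))
  cl <- classify_trends(med, perm_p, hn)
  expect_equal(cl$umbrella, "concave")
  expect_equal(cl$strongest, "preHt")
  expect_equal(cl$monotonic, "none")
  expect_equal(cl$band, "strong")

  # monotonic increasing, no umbrella support
  med2 <- med; med2[1, groups] <- c(0.2, 0.4, 0.6)
  hn2 <- list(ansi = list(increasing = hn_sig(5, 1e-6),
                          decreasing = hn_sig(-5, 1),
                          concave = hn_sig(0, 0.5),
                          convex = hn_sig(0, 0.5)))
  cl2 <- classify_trends(med2, perm_p, hn2)
  expect_equal(cl2$monotonic, "increasing")
  expect_equal(cl2$umbrella, "none")
  expect_equal(cl2$nt_end, "+")

  # an exact tie in |median| is reported, never silently broken
  med3 <- med; med3[1, groups] <- c(0.5, -0.5, 0.1)
  cl3 <- classify_trends(med3, perm_p, hn2)
  expect_equal(cl3$strongest, "tie")

  # a non-significant endpoint is described as ~0
  perm_p4 <- perm_p; perm_p4[1, "Ht"] <- 0.4
  cl4 <- classify_trends(med2, perm_p4, hn2)
  expect_equal(cl4$ht_end, "~0")
})
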