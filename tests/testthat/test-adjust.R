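test_that("cell-means fit equals the saturated linear-model least squares", {
  set.seed(42)
  n <- 50
  gender <- sample(c("F", "M"), n, replace = TRUE)
  age_class <- sample(c("17-30", "31-49", "50-86"), n, replace = TRUE)
  y <- rnorm(n, mean = 3)
  m <- fit_cell_means(y, gender, age_class)
  res <- y - predict(m, gender, age_class)
  # independent oracle: design-matrix least squares of the saturated model
  lm_res <- residuals(lm(y ~ factor(gender) * factor(age_class)))
  expect_lt(max(abs(res - unname(lm_res))), 1e-10)
  # within-cell residual sums vanish
  expect_lt(max(abs(tapply(res, paste(gender, age_class), sum))), 1e-10)
})

test_that("constant input gives all-zero residuals and unseen cells error", {
  m <- fit_cell_means(rep(7, 12), rep(c("F", "M"), 6), rep("31-49", 12))
  expect_equal(predict(m, rep(c("F", "M"), 6), rep("31-49", 12)), rep(7, 12))
  expect_error(predict(m, "F", "50-86"), class = "barotrend_missing_cell_error")
})

test_that("adjustment removes injected gender/age effects and is orthogonal", {
  co <- mini_cohort(seed = 8)
  co$rr_mean <- co$rr_mean + ifelse(co$gender == "F", 300, 0)  # gross shift
  adj <- adjust_cohort(co)
  fdiff <- abs(mean(adj$rr_mean_adj[adj$gender == "F"]) -
                 mean(adj$rr_mean_adj[adj$gender == "M"]))
  expect_lt(fdiff, 1e-10)
  # residuals orthogonal to every cell indicator
  for (g in c("F", "M")) {
    for (a in unique(co$age_class)) {
      ind <- as.numeric(co$gender == g & co$age_class == a)
      for (v in paste0(c("alpha", "hr", "sap_mean"), "_adj")) {
        expect_lt(abs(cov(adj[[v]], ind)), 1e-10)
      }
    }
  }
})

test_that("adjustment is idempotent", {
  co <- mini_cohort(seed = 9)
  adj1 <- adjust_cohort(co)
  co2 <- co
  for (v in c("alpha", proxy_names())) co2[[v]] <- adj1[[paste0(v, "_adj")]]
  adj2 <- adjust_cohort(co2)
  for (v in c("alpha", proxy_names())) {
    expect_equal(adj2[[paste0(v, "_adj")]], adj1[[paste0(v, "_adj")]],
                 tolerance = 1e-12)
  }
  expect_equal(adj2$ansi, adj1$ansi, tolerance = 1e-12)
})

test_that("ANSI is a 0-100 percent rank with midrank ties at 50", {
  co <- mini_cohort(seed = 10)
  a <- compute_ansi(co)
  expect_true(all(a >= 0 & a <= 100))
  # full tie: identical component values for everyone
  co_t <- co
  co_t[ansi_components()] <- 1
  expect_equal(compute_ansi(co_t), rep(50, nrow(co_t)))
  expect_error(compute_ansi(co[1, ]), class = "barotrend_param_error")
})

test_that("ANSI is invariant to increasing affine transforms of components", {
  co <- mini_cohort(seed = 11)
  a0 <- compute_ansi(co)
  co$rr_tp <- 3.7 * co$rr_tp + 100
  co$rr_mean <- 0.2 * co$rr_mean - 5
  expect_equal(compute_ansi(co), a0, tolerance = 1e-12)
})

test_that("ANSI correlates positively with its adjusted components", {
  co <- default_cohort_cached()
  adj <- adjust_cohort(co)
  for (v in ansi_components()) {
    expect_gt(cor(adj$ansi, adj[[paste0(v, "_adj")]], method = "spearman"), 0.2)
  }
})
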