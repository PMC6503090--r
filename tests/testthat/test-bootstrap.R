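test_that("balanced plan: every subject appears exactly B times", {
  co <- mini_cohort(seed = 5)
  B <- 37
  plan <- balanced_stratified_plan(co$stratum, B, seed = 3)
  counts <- tabulate(plan$index, nbins = nrow(co))
  expect_true(all(counts == B))
})

test_that("every replicate preserves stratum (and hence group) counts", {
  co <- default_cohort_cached()
  plan <- balanced_stratified_plan(co$stratum, B = 5, seed = 4)
  for (b in 1:5) {
    st <- table(co$stratum[plan$index[, b]])
    expect_equal(st[["preHt"]], 144L)
    expect_equal(st[["Nt3"]], 282L)
    expect_equal(st[["Ht2"]], 65L)
    gr <- table(co$group[plan$index[, b]])
    expect_equal(as.integer(gr[c("Nt", "preHt", "Ht")]), c(778L, 144L, 232L))
  }
})

test_that("B = 1 balanced plan is a within-stratum permutation", {
  co <- mini_cohort(seed = 6)
  plan <- balanced_stratified_plan(co$stratum, B = 1, seed = 9)
  idx <- plan$index[, 1]
  expect_equal(sort(idx), seq_len(nrow(co)))
  for (s in unique(co$stratum)) {
    rows <- which(co$stratum == s)
    expect_setequal(idx[rows], rows)
  }
})

test_that("a B = 1 ensemble equals the original cohort's WINcorr values", {
  co <- mini_cohort(seed = 7)
  plan <- balanced_stratified_plan(co$stratum, B = 1, seed = 2)
  ens <- bootstrap_wincorr_ensemble(co, plan, gamma = 0.1)
  expect_equal(dim(ens), c(1L, 14L, 4L))
  adj <- adjust_cohort(co)
  Y <- cbind(as.matrix(adj[paste0(proxy_names(), "_adj")]), ansi = adj$ansi)
  for (sc in analysis_scopes()) {
    rows <- if (sc == "overall") seq_len(nrow(adj)) else which(adj$group == sc)
    for (j in seq_len(14)) {
      expect_equal(ens[1, j, sc],
                   wincorr(adj$alpha_adj[rows], Y[rows, j], 0.1),
                   tolerance = 1e-12)
    }
  }
})

test_that("empty-stratum and mismatched-plan inputs error", {
  co <- mini_cohort(seed = 5)
  expect_error(balanced_stratified_plan(co$stratum, B = 0, seed = 1),
               class = "barotrend_param_error")
  expect_error(balanced_stratified_plan(c(co$stratum[-1], NA), B = 2, seed = 1),
               class = "barotrend_config_error")
  plan <- balanced_stratified_plan(rev(co$stratum), B = 2, seed = 1)
  expect_error(bootstrap_wincorr_ensemble(co, plan),
               class = "barotrend_config_error")
})

test_that("ensemble median uses the midpoint convention and a sort oracle", {
  co <- mini_cohort(seed = 5)
  plan <- balanced_stratified_plan(co$stratum, B = 8, seed = 13)
  ens <- bootstrap_wincorr_ensemble(co, plan, gamma = 0.1)
  med <- ensemble_median(ens)
  expect_equal(dim(med), c(14L, 4L))
  # sort-based oracle on random cells
  set.seed(99)
  for (i in 1:40) {
    cm <- sample(comparison_names(), 1)
    sc <- sample(analysis_scopes(), 1)
    v <- sort(ens[, cm, sc])
    oracle <- (v[4] + v[5]) / 2  # even count midpoint, by direct sort
    expect_equal(med[cm, sc], oracle, tolerance = 1e-12)
  }
  # constant and simple even-count cases
  ens2 <- ens
  ens2[, 1, 1] <- 0.3
  expect_equal(ensemble_median(ens2)[1, 1], 0.3)
  ens2[1:4, 1, 1] <- c(0.1, 0.2, 0.3, 0.4)
  ens2[5:8, 1, 1] <- NA  # flagged cells are excluded
  expect_equal(ensemble_median(ens2)[1, 1], 0.25)
})

test_that("balancing reduces the simulation error of the ensemble mean", {
  co <- mini_cohort(seed = 14)
  mean_of <- function(balanced, seed) {
    plan <- balanced_stratified_plan(co$stratum, B = 200, seed = seed,
                                     balanced = balanced)
    ens <- bootstrap_wincorr_ensemble(co, plan, gamma = 0.1)
    mean(ens[, "ansi", "overall"])
  }
  bal <- vapply(1:10, function(s) mean_of(TRUE, 500 + s), numeric(1))
  ord <- vapply(1:10, function(s) mean_of(FALSE, 500 + s), numeric(1))
  expect_lte(var(bal), var(ord))
})
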