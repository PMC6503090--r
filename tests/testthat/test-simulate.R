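test_that("single-factor construction hits the configured correlations", {
  set.seed(1)
  # degenerate loading 1: proxy identical to the factor
  X <- sample_single_factor(c(p = 1), 100)
  expect_equal(X[, "p"], X[, "alpha"], tolerance = 1e-12)
  # loading 0: independence
  X0 <- sample_single_factor(c(p = 0), 1e5)
  expect_lt(abs(cor(X0[, "alpha"], X0[, "p"])), 0.02)
  # loading 0.6 at n = 1e6: sample r within +/- 0.01
  X6 <- sample_single_factor(c(p = 0.6), 1e6)
  expect_lt(abs(cor(X6[, "alpha"], X6[, "p"]) - 0.6), 0.01)
  # proxy-proxy correlation is the product of loadings
  Xp <- sample_single_factor(c(a = 0.8, b = -0.5), 2e5)
  expect_lt(abs(cor(Xp[, "a"], Xp[, "b"]) - (0.8 * -0.5)), 0.015)
  expect_error(sample_single_factor(1.2, 10),
               class = "barotrend_calibration_error")
  expect_error(sample_single_factor(0.5, 1), class = "barotrend_param_error")
})

test_that("generated cohorts honour the design counts exactly, every seed", {
  d <- default_design()
  for (s in c(2, 77, 90210)) {
    co <- generate_cohort(seed = s)
    expect_equal(nrow(co), 1154L)
    st <- table(co$stratum)[d$strata$stratum]
    expect_equal(as.integer(st), d$strata$count)
    cells <- aggregate(rep(1L, nrow(co)),
                       by = co[c("gender", "age_class", "group")], FUN = sum)
    m <- merge(d$cell_counts, cells, by = c("gender", "age_class", "group"))
    expect_equal(m$x, m$count)
    # labels consistent with SAP values
    expect_silent(validate_cohort(co, d))
  }
})

test_that("cohort generation is deterministic and CSV round-trips", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(design = mini_design(), seed = 42), f1)
  write_cohort_csv(generate_cohort(design = mini_design(), seed = 42), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_cohort_csv(f1, mini_design())
  expect_equal(nrow(back), 72L)
  expect_true(all(c("age_class", "alpha", proxy_names()) %in% names(back)))
})

test_that("plain-proxy loadings are recovered in the population mean", {
  # mean sample r over many cohorts within 3 Monte-Carlo SEs of the loading
  L <- 0.45
  calib <- default_calibration()
  calib[calib$group == "preHt", "hr"] <- L
  rs <- vapply(1:60, function(i) {
    co <- generate_cohort(design = mini_design(), effects = zero_effects(),
                          calib = calib, contamination_fraction = 0,
                          seed = 1000 + i)
    cor(co$alpha[co$group == "preHt"], co$hr[co$group == "preHt"])
  }, numeric(1))
  se <- sd(rs) / sqrt(length(rs))
  # small-n Pearson bias is O(1/n) ~ 0.01 at n = 24; allow it alongside 3 SE
  expect_lt(abs(mean(rs) - L), 3 * se + 0.015)
})

test_that("zero effects leave per-cell means near the configured location", {
  co <- generate_cohort(effects = zero_effects(), contamination_fraction = 0,
                        seed = 12)
  sc <- default_scales()
  loc_hr <- sc$location[sc$variable == "hr"]
  sd_hr <- sc$scale[sc$variable == "hr"]
  cell_means <- tapply(co$hr, paste(co$gender, co$age_class), mean)
  # each cell has >= 100 subjects; means within 4 SEs of the location
  cell_n <- tapply(co$hr, paste(co$gender, co$age_class), length)
  expect_true(all(abs(cell_means - loc_hr) < 4 * sd_hr / sqrt(cell_n)))
})

test_that("contamination hurts Pearson more than the Winsorized coefficient", {
  L <- 0.5
  calib <- default_calibration()
  for (g in sap_groups()) calib[calib$group == g, "rr_hfa"] <- L
  dev_p <- dev_w <- numeric(40)
  for (i in 1:40) {
    co <- generate_cohort(design = mini_design(), effects = zero_effects(),
                          calib = calib, contamination_fraction = 0.05,
                          contamination_scale = 6, seed = 3000 + i)
    dev_p[i] <- abs(cor(co$alpha, co$rr_hfa) - L)
    dev_w[i] <- abs(wincorr(co$alpha, co$rr_hfa, 0.1) - L)
  }
  expect_gt(mean(dev_p), mean(dev_w))
})
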