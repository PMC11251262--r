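test_that("IQR outlier rule flags exactly the planted extreme value", {
  set.seed(1)
  n <- 50
  scans <- data.frame(subject = sprintf("S%02d", 1:n), age = 14,
                      roi01 = seq_len(n), roi02 = rnorm(n, 100, 5))
  scans$roi01[17] <- 1e6
  fl <- flag_gmv_outliers(scans)
  expect_identical(fl$subjects, "S17")
  expect_identical(fl$flags$roi, "roi01")

  # all-identical values: IQR = 0, nothing differs from the constant
  same <- data.frame(subject = sprintf("S%02d", 1:10), age = 14, roi01 = 5)
  expect_length(flag_gmv_outliers(same)$subjects, 0)
  # ... but a deviating value is flagged under the zero-IQR convention
  same$roi01[3] <- 6
  expect_identical(flag_gmv_outliers(same)$subjects, "S03")

  # infinite k disables the rule entirely
  expect_length(flag_gmv_outliers(scans, k_iqr = Inf)$subjects, 0)
  expect_error(flag_gmv_outliers(scans[0, ]), "empty")
})

test_that("noise-free data yields exact subject slopes", {
  toy <- make_toy_scans(n = 15, slope_sd = 4, resid_sd = 0)
  fit <- fit_roi_lmm(toy, "roi01", covariates = character(0))
  truth <- attr(toy, "true_slopes")
  expect_equal(unname(fit$subject_slope[names(truth)]), unname(truth),
               tolerance = 1e-6)
})

test_that("EB slopes match the explicit GLS/BLUP oracle on a 20-subject toy", {
  toy <- make_toy_scans(n = 20, slope_sd = 5, resid_sd = 3)
  fit <- fit_roi_lmm(toy, "roi01", covariates = character(0))
  tc <- toy$age - mean(toy$age)
  X <- cbind(1, tc)
  oracle <- gls_blup_oracle(toy$roi01, X, tc, toy$subject,
                            tau2 = fit$tau2, sigma2 = fit$sigma2)
  expect_equal(unname(fit$eb_slope), unname(oracle$blup[names(fit$eb_slope)]),
               tolerance = 1e-6)
  expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-6)
})

test_that("REML recovers known variance components at n = 500 x 3", {
  set.seed(77)
  tau <- 6; sigma <- 4
  toy <- make_toy_scans(n = 500, slope_sd = tau, resid_sd = sigma, seed = 77)
  fit <- fit_roi_lmm(toy, "roi01", covariates = character(0))
  expect_lt(abs(fit$tau2 - tau^2) / tau^2, 0.15)
  expect_lt(abs(fit$sigma2 - sigma^2) / sigma^2, 0.15)
})

test_that("EB slopes are contractions of per-subject OLS residual slopes", {
  toy <- make_toy_scans(n = 40, slope_sd = 5, resid_sd = 6, seed = 3)
  fit <- fit_roi_lmm(toy, "roi01", covariates = character(0))
  tc <- toy$age - mean(toy$age)
  marg <- toy$roi01 - cbind(1, tc) %*% fit$beta
  for (s in names(fit$eb_slope)) {
    i <- toy$subject == s
    ols <- sum(tc[i] * marg[i]) / sum(tc[i]^2)
    expect_lte(abs(fit$eb_slope[[s]]), abs(ols) + 1e-8)
  }
})

test_that("EB slopes are invariant to a constant age shift", {
  toy <- make_toy_scans(n = 25, seed = 8)
  f1 <- fit_roi_lmm(toy, "roi01", covariates = character(0))
  toy2 <- toy
  toy2$age <- toy2$age + 7
  f2 <- fit_roi_lmm(toy2, "roi01", covariates = character(0))
  expect_equal(f1$eb_slope, f2$eb_slope, tolerance = 1e-6)
})

test_that("subjects with fewer than two scans are rejected", {
  toy <- make_toy_scans(n = 10)
  toy <- toy[-c(1, 2), ]  # subject T01 left with one row
  expect_error(fit_roi_lmm(toy, "roi01", covariates = character(0)), "T01")
})

test_that("rank-deficient covariates are reported by name", {
  toy <- make_toy_scans(n = 12)
  toy$c1 <- rep(1:3, length.out = nrow(toy))
  toy$c2 <- toy$c1 * 2
  expect_error(fit_roi_lmm(toy, "roi01", covariates = c("c1", "c2")),
               "rank deficient")
})

test_that("trajectory matrix columns equal independent per-ROI fits", {
  toy <- make_toy_scans(n = 15, seed = 10)
  toy$roi02 <- toy$roi01  # identical data -> identical columns
  set.seed(11)
  toy$roi03 <- 50 + rnorm(nrow(toy), 0, 4)
  tm <- build_trajectory_matrix(toy, covariates = character(0))
  expect_identical(tm[, "roi01"], tm[, "roi02"])
  single <- fit_roi_lmm(toy, "roi03", covariates = character(0))
  expect_equal(tm[, "roi03"], single$subject_slope[rownames(tm)])
})

test_that("noise-free three-group cohort gives exactly three distinct rows", {
  cfg <- tiny_config(n_subjects = 60, slope_sd = 0, slope_roi_sd = 0,
                     resid_sd = 0, p_missing_visit = 0, cpg_slope_b = 0,
                     beta_sex = 0, site_effects = rep(0, 4), beta_hand = 0,
                     beta_icv = 0, n_rois = 5)
  b <- simulate_cohort(cfg)
  tm <- build_trajectory_matrix(b$scans, covariates = character(0))
  distinct <- unique(round(unclass(tm), 6))
  expect_equal(nrow(distinct), 3)
})
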