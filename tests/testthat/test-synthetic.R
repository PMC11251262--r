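test_that("noise-free cohorts reproduce the group slope means exactly", {
  cfg <- tiny_config(slope_sd = 0, slope_roi_sd = 0, resid_sd = 0,
                     p_missing_visit = 0, cpg_slope_b = 0,
                     beta_sex = 0, site_effects = rep(0, 4), beta_hand = 0,
                     beta_icv = 0, n_rois = 6)
  b <- simulate_cohort(cfg)
  # per-subject OLS slope per ROI must equal the group's slope_means entry
  for (s in b$subjects$subject[c(1, 50, 120)]) {
    sc <- b$scans[b$scans$subject == s, ]
    g <- b$subjects$true_group[b$subjects$subject == s]
    for (r in seq_len(6)) {
      ols <- coef(lm(sc[[sprintf("roi%02d", r)]] ~ sc$age))[2]
      expect_equal(unname(ols), unname(cfg$slope_means[g, r]), tolerance = 1e-10)
    }
  }
})

test_that("identical configs give identical bundles (determinism)", {
  cfg <- tiny_config()
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1, b2)
  a1 <- simulate_adult_cohort(cfg, data.frame(id = c("rs1", "rs2"),
                                              beta = c(0.2, -0.1),
                                              maf = c(0.3, 0.4)))
  a2 <- simulate_adult_cohort(cfg, data.frame(id = c("rs1", "rs2"),
                                              beta = c(0.2, -0.1),
                                              maf = c(0.3, 0.4)))
  expect_identical(a1, a2)
})

test_that("realized group counts sit within multinomial 99% bounds", {
  cfg <- sim_config(n_subjects = 1500, p_missing_visit = 0, n_snps = 10,
                    n_cpgs = 10, seed = 9)
  b <- simulate_cohort(cfg)
  counts <- table(factor(b$subjects$true_group, levels = 1:3))
  for (g in 1:3) {
    lo <- qbinom(0.005, 1500, cfg$group_fractions[g])
    hi <- qbinom(0.995, 1500, cfg$group_fractions[g])
    expect_gte(counts[g], lo)
    expect_lte(counts[g], hi)
  }
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(group_fractions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(sim_config(n_subjects = 20, group_fractions = c(0.48, 0.48, 0.04)),
               "degenerate group")
  expect_error(sim_config(causal_snp_or = 0), "causal_snp_or")
  expect_error(sim_config(adult_outcome_rho = 1), "adult_outcome_rho")
  expect_error(sim_config(ref_age_range = c(25, 5)), "increasing")
  expect_error(sim_config(cpg_env_a = 0.5, env_sd = 0), "env")
})

test_that("null causal OR makes the causal SNP independent of group", {
  cfg <- sim_config(n_subjects = 3000, causal_snp_or = 1, n_snps = 20,
                    n_cpgs = 10, p_missing_visit = 0, geno_missing_rate = 0,
                    seed = 5)
  b <- simulate_cohort(cfg)
  cs <- b$truth$causal_snp
  d <- b$genotypes$dosages[, cs]
  p <- suppressWarnings(chisq.test(table(d, b$subjects$true_group))$p.value)
  expect_gt(p, 0.001)
})

test_that("genotype frequencies follow Hardy-Weinberg at the configured MAF", {
  cfg <- tiny_config(n_subjects = 4000, maf_range = c(0.5, 0.5), n_snps = 5,
                     geno_missing_rate = 0, causal_snp_or = 1)
  b <- simulate_cohort(cfg)
  d <- b$genotypes$dosages[, 1]
  n <- length(d)
  # binomial oracle: 99.9% bounds for each genotype class at HWE(0.5)
  for (cls in 0:2) {
    pr <- c(0.25, 0.5, 0.25)[cls + 1]
    cnt <- sum(d == cls)
    expect_gte(cnt, qbinom(5e-4, n, pr))
    expect_lte(cnt, qbinom(1 - 5e-4, n, pr))
  }
})

test_that("methylation values are valid and the environment path is calibrated", {
  cfg <- tiny_config(n_subjects = 2000, n_cpgs = 20)
  g <- rep(1:3, length.out = 2000)
  m0 <- simulate_methylation_env(tiny_config(n_subjects = 2000, n_cpgs = 20,
                                             cpg_env_a = 0), g)
  expect_true(all(m0$table > 0 & m0$table < 1))
  ci <- which(m0$markers$causal)
  expect_lt(abs(cor(m0$env, m0$table[, ci])), 3 / sqrt(2000))

  m <- simulate_methylation_env(cfg, g)
  # analytic correlation of env with logit(beta) under the linear-Gaussian
  # logit model: a*sd_env / sqrt(a^2 sd_env^2 + shift-var + noise^2)
  lg <- qlogis(m$table[, ci])
  shift_var <- var(cfg$cpg_group2_shift * (g == 2))
  r_true <- cfg$cpg_env_a /
    sqrt(cfg$cpg_env_a^2 + shift_var + cfg$cpg_noise_sd^2)
  expect_lt(abs(cor(m$env, lg) - r_true), 0.06)
})

test_that("reference cohort recovers its generating quadratic", {
  cfg <- tiny_config(n_ref_subjects = 400, ref_resid_sd = 0)
  ref <- simulate_reference(cfg)
  expect_true(all(c("study", "total_gmv") %in% names(ref)))
  expect_true(all(ref$study %in% c("ref1", "ref2")))
  gen <- attr(ref, "generating")
  # exact least squares on noise-free data reproduces the per-ROI quadratic
  r1 <- ref[ref$study == "ref1", ]
  fit <- lm(roi01 ~ age + I(age^2), data = r1)
  co <- coef(fit)
  expect_equal(unname(co[3]), -gen$curv[1], tolerance = 1e-8)
  expect_equal(unname(-co[2] / (2 * co[3])), gen$peak_age[1], tolerance = 1e-8)
})

test_that("adult outcomes decorrelate when rho is zero", {
  cfg <- tiny_config(n_adult = 2000, adult_outcome_rho = 0)
  w <- data.frame(id = sprintf("rs%d", 1:20), beta = rnorm(20, 0, 0.1),
                  maf = runif(20, 0.1, 0.5))
  a <- simulate_adult_cohort(cfg, w)
  pgs <- as.vector(a$genotypes$dosages %*% w$beta)
  expect_lt(abs(cor(pgs, a$outcomes$income)), 3 / sqrt(2000))
})

test_that("cohort artifacts round-trip through write_cohort and load_tables", {
  cfg <- tiny_config()
  b <- simulate_cohort(cfg)
  dir <- tempfile("bundle_")
  write_cohort(b, dir)
  lt <- load_tables(list(
    scans = file.path(dir, "scans.csv"),
    subjects = file.path(dir, "subjects.csv"),
    genotypes = file.path(dir, "genotypes.csv"),
    snps = file.path(dir, "snps.tsv"),
    methylation = file.path(dir, "methylation.csv"),
    cpgs = file.path(dir, "cpgs.tsv"),
    environment = file.path(dir, "environment.csv"),
    outcomes = file.path(dir, "outcomes.csv")))
  expect_equal(nrow(lt$scans), nrow(b$scans))
  expect_equal(dim(lt$genotypes$dosages), dim(b$genotypes$dosages))
  expect_equal(unname(lt$genotypes$dosages[3, 7]),
               unname(b$genotypes$dosages[3, 7]))
  unlink(dir, recursive = TRUE)
})
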