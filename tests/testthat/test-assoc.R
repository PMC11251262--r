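geno_table <- function(D, chr = NULL, pos = NULL) {
  p <- ncol(D)
  if (is.null(chr)) chr <- rep(1L, p)
  if (is.null(pos)) pos <- seq_len(p) * 1000L
  structure(list(
    dosages = D,
    markers = data.frame(id = colnames(D), chr = chr, pos = pos,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)),
    class = "genotype_table")
}

test_that("QC applies the stated thresholds with inclusive boundaries", {
  set.seed(17)
  n <- 100
  # 40 filler SNPs keep per-subject missing rates below the subject filter
  D <- matrix(rbinom(n * 44, 2, 0.3), n, 44,
              dimnames = list(sprintf("S%03d", 1:n), paste0("rs", 1:44)))
  D[, 1] <- rep(c(0, 1, 2), c(25, 50, 25))          # exact HWE: retained
  D[, 2] <- rep(c(0, 2), c(50, 50))                 # extreme HWE violation
  D[1:6, 3] <- NA                                   # 94% call rate: dropped
  D[1:5, 4] <- NA                                   # 95% exactly: retained
  D[6:n, 4] <- rep(c(0, 1, 2), length.out = 95)
  qc <- qc_genotypes(geno_table(D))
  kept <- qc$genotypes$markers$id
  expect_true("rs1" %in% kept)
  expect_false("rs2" %in% kept)   # chi-square = n = 100, p ~ 1.5e-23 < 1e-10
  expect_false("rs3" %in% kept)
  expect_true("rs4" %in% kept)
  expect_equal(qc$report$reason[qc$report$id == "rs2"], "hwe")
  expect_equal(qc$report$reason[qc$report$id == "rs3"], "call_rate")
  # hand chi-square for the 50/0/50 marker
  chi <- sum((c(50, 0, 50) - c(25, 50, 25))^2 / c(25, 50, 25))
  expect_equal(chi, 100)

  # subjects failing the missing-rate filter go first
  D2 <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
               dimnames = list(sprintf("S%03d", 1:n), paste0("m", 1:20)))
  D2[7, 1:5] <- NA  # 25% missing
  qc2 <- qc_genotypes(geno_table(D2))
  expect_false("S007" %in% rownames(qc2$genotypes$dosages))
})

test_that("association scan recovers a planted effect and skips degenerate SNPs", {
  set.seed(19)
  n <- 2000
  D <- matrix(rbinom(n * 10, 2, 0.3), n, 10,
              dimnames = list(sprintf("S%04d", 1:n), paste0("rs", 1:10)))
  D[, 10] <- 1  # constant: skipped
  y <- 0.25 * as.vector(scale(D[, 4])) + rnorm(n)
  names(y) <- rownames(D)
  gw <- gwas_scan(y, geno_table(D))
  expect_equal(gw$note[10], "skipped_monomorphic")
  expect_equal(which.min(gw$p[1:9]), 4)
  beta_std <- gw$beta[4] * sd(D[, 4])
  expect_lt(abs(beta_std - 0.25), 2 * gw$se[4] * sd(D[, 4]))
  # missing dosages drop subjects for that SNP only
  D2 <- D; D2[1:100, 2] <- NA
  gw2 <- gwas_scan(y, geno_table(D2))
  expect_equal(gw2$n[2], n - 100)
  expect_equal(gw2$n[3], n)
})

test_that("SMOTE interpolates along minority segments and balances classes", {
  X <- rbind(c(0, 0), c(1, 2), matrix(5 + runif(20), 10, 2))
  y <- c("min", "min", rep("maj", 10))
  bal <- smote(X, y, k_neighbors = 1, seed = 2)
  expect_equal(sum(bal$y == "min"), sum(bal$y == "maj"))
  synth <- bal$X[-(1:12), , drop = FALSE]
  # convex combinations of the two minority points stay on the segment
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 1))
  expect_true(all(synth[, 2] >= 0 & synth[, 2] <= 2))
  expect_equal(synth[, 2], 2 * synth[, 1], tolerance = 1e-12)

  # balanced input returned unchanged; singleton minority rejected
  Xb <- matrix(rnorm(8), 4, 2)
  expect_identical(smote(Xb, c(0, 0, 1, 1))$X, Xb)
  expect_error(smote(X[-1, ], y[-1]), "single")
  b1 <- smote(X, y, k_neighbors = 1, seed = 7)
  b2 <- smote(X, y, k_neighbors = 1, seed = 7)
  expect_identical(b1, b2)
})

test_that("EWAS pinpoints a planted CpG and skips constants", {
  set.seed(23)
  n <- 400
  g <- stats::setNames(rep(c(1, 2), each = n / 2), sprintf("S%04d", 1:n))
  B <- matrix(plogis(rnorm(n * 12, 0, 0.5)), n, 12,
              dimnames = list(names(g), sprintf("cg%02d", 1:12)))
  B[, 5] <- plogis(rnorm(n, 0, 0.5) + 0.9 * (g == 2))
  B[, 12] <- 0.4
  meth <- list(values = B,
               markers = data.frame(id = colnames(B), chr = 1L,
                                    pos = seq_len(12) * 100L))
  ew <- ewas_scan(g, c(2, 1), meth)
  expect_equal(ew$note[12], "skipped_constant")
  expect_equal(which.min(ew$p), 5)
  expect_true(all(ew$p_adj >= ew$p - 1e-12, na.rm = TRUE))

  ew_s <- ewas_scan(g[c(rep(TRUE, 30), rep(FALSE, 170), rep(TRUE, 200))],
                    c(2, 1), meth, use_smote = TRUE, seed = 4)
  expect_equal(which.min(ew_s$p), 5)
})

test_that("PGS arithmetic, allele flipping and linearity hold", {
  D <- matrix(2, 1, 1, dimnames = list("S1", "rs1"))
  g <- geno_table(D)
  s <- data.frame(id = "rs1", beta = 0.3, p = 1e-9)
  pg <- compute_pgs(g, s, thresholds = 1)
  expect_equal(unname(pg$score), 0.3)  # 0.3 * 2 / (2 * 1)

  set.seed(29)
  D2 <- matrix(rbinom(200 * 6, 2, 0.4), 200, 6,
               dimnames = list(sprintf("S%03d", 1:200), paste0("rs", 1:6)))
  g2 <- geno_table(D2)
  s2 <- data.frame(id = paste0("rs", 1:6), beta = rnorm(6), p = runif(6),
                   effect_allele = "G")
  s2flip <- s2; s2flip$effect_allele <- "A"  # = table ref -> dosage flipped
  a <- compute_pgs(g2, s2, thresholds = 1)$score
  b <- compute_pgs(g2, s2flip, thresholds = 1)$score
  expect_equal(cor(a, b), -1, tolerance = 1e-12)

  # linearity across disjoint marker sets at a common threshold
  sA <- s2[1:2, ]; sB <- s2[3:6, ]
  full <- compute_pgs(g2, s2, thresholds = 1)$score
  pa <- compute_pgs(g2, sA, thresholds = 1)$score
  pb <- compute_pgs(g2, sB, thresholds = 1)$score
  expect_equal(full, (2 * pa + 4 * pb) / 6, tolerance = 1e-12)

  expect_error(compute_pgs(g2, data.frame(id = "zz", beta = 1, p = 0.5)),
               "overlapping")
})

test_that("clumping matches the brute-force greedy oracle", {
  set.seed(31)
  n <- 300
  base <- rbinom(n, 2, 0.4)
  D <- cbind(
    s1 = base,
    s2 = ifelse(runif(n) < 0.9, base, rbinom(n, 2, 0.4)),  # high LD with s1
    s3 = rbinom(n, 2, 0.3),
    s4 = rbinom(n, 2, 0.3),
    s5 = ifelse(runif(n) < 0.95, base, rbinom(n, 2, 0.4)),
    s6 = rbinom(n, 2, 0.2))
  rownames(D) <- sprintf("S%03d", 1:n)
  pos <- c(1e5, 1.5e5, 2e5, 6e6, 1.2e5, 1e5)
  chr <- c(1, 1, 1, 1, 1, 2)
  summ <- data.frame(id = colnames(D), chr = chr, pos = pos,
                     p = c(1e-8, 1e-6, 1e-4, 1e-3, 1e-5, 1e-7))
  sel <- clump_locus(summ, geno_table(D, chr = chr, pos = pos),
                     window_kb = 250, r2_max = 0.1)
  oracle <- greedy_clump_oracle(summ, D, window = 250000, r2_max = 0.1)
  expect_identical(sel, oracle)
  expect_true("s1" %in% sel)
  expect_false("s5" %in% sel)  # r2 with s1 ~ 0.9 within the window

  # mutually uncorrelated far-apart SNPs each become their own index
  Du <- matrix(rbinom(n * 3, 2, 0.5), n, 3,
               dimnames = list(rownames(D), c("u1", "u2", "u3")))
  su <- data.frame(id = colnames(Du), chr = 1, pos = c(1e6, 5e6, 9e6),
                   p = c(0.2, 0.01, 0.1))
  expect_setequal(clump_locus(su, geno_table(Du, pos = su$pos)), colnames(Du))
})
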