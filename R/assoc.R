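#' Marker-level and subject-level genotype quality control
#'
#' Subjects with more than `subj_missing` missing dosages are removed first;
#' then SNPs are filtered by call rate (boundary inclusive: exactly 95\%
#' is retained), minor allele frequency, and a 1-df chi-square
#' Hardy-Weinberg test on hard calls (dosages rounded to 0/1/2).
#'
#' @param geno a `genotype_table`.
#' @param call_rate minimum SNP call rate.
#' @param maf minimum minor-allele frequency.
#' @param hwe_p Hardy-Weinberg chi-square p-value floor.
#' @param subj_missing maximum subject missing rate.
#' @return list: `genotypes` (filtered `genotype_table`) and `report`
#'   (data.frame: type, id, reason, value).
#' @export
qc_genotypes <- function(geno, call_rate = 0.95, maf = 0.001, hwe_p = 1e-10,
                         subj_missing = 0.10) {
  D <- geno$dosages
  if (!nrow(D) || !ncol(D)) stop("empty genotype table", call. = FALSE)
  report <- list()
  subj_miss <- rowMeans(is.na(D))
  bad_subj <- subj_miss > subj_missing
  if (any(bad_subj))
    report$subj <- data.frame(type = "subject", id = rownames(D)[bad_subj],
                              reason = "missing_rate", value = subj_miss[bad_subj],
                              stringsAsFactors = FALSE)
  D <- D[!bad_subj, , drop = FALSE]
  if (!nrow(D)) stop("all subjects excluded by missing-rate filter", call. = FALSE)

  cr <- colMeans(!is.na(D))
  freq <- colMeans(D, na.rm = TRUE) / 2
  maf_obs <- pmin(freq, 1 - freq)
  hwe <- apply(D, 2, function(d) {
    h <- round(d[!is.na(d)])
    n <- length(h)
    if (!n) return(1)
    p <- mean(h) / 2
    if (p <= 0 || p >= 1) return(1)
    obs <- c(sum(h == 0), sum(h == 1), sum(h == 2))
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stats::pchisq(sum((obs - expd)^2 / expd), df = 1, lower.tail = FALSE)
  })
  drop_cr <- cr < call_rate
  drop_maf <- !drop_cr & maf_obs < maf
  drop_hwe <- !drop_cr & !drop_maf & hwe < hwe_p
  mk <- function(idx, reason, value)
    if (any(idx)) data.frame(type = "snp", id = colnames(D)[idx], reason = reason,
                             value = value[idx], stringsAsFactors = FALSE)
  report$cr <- mk(drop_cr, "call_rate", cr)
  report$maf <- mk(drop_maf, "maf", maf_obs)
  report$hwe <- mk(drop_hwe, "hwe", hwe)
  keep <- !(drop_cr | drop_maf | drop_hwe)
  out <- structure(list(dosages = D[, keep, drop = FALSE],
                        markers = geno$markers[keep, , drop = FALSE]),
                   class = "genotype_table")
  rownames(out$markers) <- NULL
  list(genotypes = out,
       report = do.call(rbind, c(report[!vapply(report, is.null, TRUE)],
                                 list(make.row.names = FALSE))))
}

#' Per-SNP association scan on a quantitative phenotype
#'
#' Ordinary least squares of the phenotype on each SNP dosage plus
#' covariates, t-test on the dosage coefficient. Subjects with a missing
#' dosage are dropped for that SNP; constant dosage columns are skipped.
#'
#' @param phenotype named numeric vector (names = subject ids) or a
#'   data.frame `subject`, `score`.
#' @param geno a `genotype_table`.
#' @param covariates optional data.frame keyed by `subject`.
#' @param sig_threshold genome-wide significance flag level.
#' @return data.frame of class `assoc_result`: id, chr, pos, ref, alt, beta,
#'   se, p, n, genomewide, note.
#' @export
gwas_scan <- function(phenotype, geno, covariates = NULL, sig_threshold = 5e-8) {
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype$score, phenotype$subject)
  D <- geno$dosages
  shared <- intersect(rownames(D), names(phenotype))
  D <- D[shared, , drop = FALSE]
  y <- phenotype[shared]
  Xc <- if (!is.null(covariates)) {
    cv <- covariates[match(shared, covariates$subject),
                     setdiff(names(covariates), "subject"), drop = FALSE]
    covariate_matrix(cv, n = length(shared))
  } else covariate_matrix(NULL, n = length(shared))
  res <- lapply(seq_len(ncol(D)), function(j) {
    d <- D[, j]
    ok <- !is.na(d)
    if (sum(ok) < ncol(Xc) + 2 || stats::var(d[ok]) == 0)
      return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = sum(ok), note = "skipped_monomorphic"))
    f <- ols_fit(y[ok], cbind(Xc[ok, , drop = FALSE], dosage = d[ok]))
    if (is.null(f))
      return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = sum(ok), note = "skipped_rank_deficient"))
    k <- length(f$coef)
    data.frame(beta = f$coef[k], se = f$se[k], p = f$p[k], n = sum(ok), note = "")
  })
  tab <- cbind(geno$markers[, c("id", "chr", "pos", "ref", "alt")],
               do.call(rbind, res))
  tab$genomewide <- !is.na(tab$p) & tab$p < sig_threshold
  rownames(tab) <- NULL
  class(tab) <- c("assoc_result", "data.frame")
  tab
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a two-class data set by generating synthetic minority rows
#' `x_i + u (x_nn - x_i)` with `u ~ U(0, 1)` and `x_nn` one of the k nearest
#' minority neighbours (Euclidean). Balanced input is returned unchanged.
#'
#' @param X numeric matrix of predictors.
#' @param y two-class label vector.
#' @param k_neighbors neighbour count (capped at minority size - 1 with a
#'   warning).
#' @param seed integer seed.
#' @return list `X`, `y` with classes balanced to equal counts.
#' @export
smote <- function(X, y, k_neighbors = 5, seed = 1L) {
  X <- as.matrix(X)
  tabs <- sort(table(y))
  if (length(tabs) != 2) stop("smote needs exactly two classes", call. = FALSE)
  n_min <- tabs[1]; n_maj <- tabs[2]
  if (n_min == n_maj) return(list(X = X, y = y))
  if (n_min < 2) stop("minority class has a single member; no neighbour exists",
                      call. = FALSE)
  min_class <- names(tabs)[1]
  if (k_neighbors >= n_min) {
    warning("k_neighbors >= minority size; capped at ", n_min - 1, call. = FALSE)
    k_neighbors <- n_min - 1
  }
  Xm <- X[y == min_class, , drop = FALSE]
  dmat <- as.matrix(stats::dist(Xm))
  diag(dmat) <- Inf
  nn_raw <- apply(dmat, 1, function(d) order(d)[seq_len(k_neighbors)])
  nn <- if (is.matrix(nn_raw)) t(nn_raw) else matrix(nn_raw, ncol = 1)
  n_new <- n_maj - n_min
  with_seed(seed, {
    i <- sample.int(n_min, n_new, replace = TRUE)
    jj <- nn[cbind(i, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- stats::runif(n_new)
    Xnew <- Xm[i, , drop = FALSE] + u * (Xm[jj, , drop = FALSE] - Xm[i, , drop = FALSE])
    list(X = rbind(X, Xnew),
         y = c(y, rep(min_class, n_new)))
  })
}

#' Per-CpG logistic epigenome-wide association scan
#'
#' Logistic regression of the class label on each CpG beta value plus the
#' supplied covariate columns, Wald test on the beta-value coefficient.
#' When `use_smote` is set the joint (CpG, covariates) predictor block is
#' oversampled to class balance before each fit. Separation falls back to a
#' ridge-regularized fit with a warning; constant CpGs are skipped.
#'
#' @param labels named group vector.
#' @param pair the two group labels compared (`pair[1]` coded 1).
#' @param meth methylation list with `values` (subjects x CpGs) and `markers`.
#' @param covariates optional data.frame keyed by `subject` (generic columns:
#'   sex, batch, composition PCs as supplied).
#' @param use_smote oversample the minority class before fitting.
#' @param seed seed for the SMOTE draws.
#' @param sig_threshold genome-wide significance flag level.
#' @return data.frame of class `assoc_result`: id, chr, pos, beta, se, p, n,
#'   p_adj, genomewide, note.
#' @export
ewas_scan <- function(labels, pair, meth, covariates = NULL, use_smote = FALSE,
                      seed = 1L, sig_threshold = 5e-8) {
  stopifnot(!is.null(names(labels)))
  B <- meth$values
  g <- labels[rownames(B)]
  keep <- g %in% pair
  if (!any(g[keep] == pair[1]) || !any(g[keep] == pair[2]))
    stop("both classes must be present", call. = FALSE)
  B <- B[keep, , drop = FALSE]
  y <- as.numeric(g[keep] == pair[1])
  Xc <- if (!is.null(covariates)) {
    cv <- covariates[match(rownames(B), covariates$subject),
                     setdiff(names(covariates), "subject"), drop = FALSE]
    covariate_matrix(cv, n = nrow(B))[, -1, drop = FALSE]
  } else NULL
  res <- lapply(seq_len(ncol(B)), function(j) {
    x <- B[, j]
    if (stats::var(x) == 0)
      return(data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                        n = length(x), note = "skipped_constant"))
    Xj <- cbind(cpg = x, Xc)
    yj <- y
    if (use_smote) {
      bal <- smote(Xj, yj, seed = substream_seed(seed, paste0("cpg", j)))
      Xj <- bal$X; yj <- as.numeric(bal$y)
    }
    fit <- tryCatch({
      gf <- suppressWarnings(stats::glm.fit(cbind(1, Xj), yj,
                                            family = stats::binomial()))
      sm <- sqrt(diag(chol2inv(gf$qr$qr[seq_len(gf$rank), seq_len(gf$rank), drop = FALSE])))
      co <- gf$coefficients
      if (!gf$converged || any(!is.finite(co)) || abs(co[2]) > 50) NULL
      else list(beta = co[2], se = sm[2])
    }, error = function(e) NULL)
    note <- ""
    if (is.null(fit)) {
      rf <- ridge_logistic(yj, Xj, ridge = 1e-3)
      fit <- list(beta = rf$coef[2], se = rf$se[2])
      note <- "ridge_fallback"
      warning("separation for CpG ", colnames(B)[j],
              "; ridge-regularized fit used", call. = FALSE)
    }
    z <- fit$beta / fit$se
    data.frame(beta = unname(fit$beta), se = unname(fit$se),
               p = 2 * stats::pnorm(-abs(z)), n = length(yj), note = note)
  })
  tab <- cbind(meth$markers[, c("id", "chr", "pos")], do.call(rbind, res))
  tab$p_adj <- NA_real_
  ok <- !is.na(tab$p)
  tab$p_adj[ok] <- bh_fdr(tab$p[ok])
  tab$genomewide <- ok & tab$p < sig_threshold
  rownames(tab) <- NULL
  class(tab) <- c("assoc_result", "data.frame")
  tab
}

#' Polygenic scores with p-value threshold averaging
#'
#' For each threshold T the score is the effect-weighted dosage sum over the
#' markers with `p <= T`, divided by twice the number of observed markers
#' (average-per-allele convention); the final score is the mean over
#' thresholds with a nonempty marker set. When a summary effect allele equals
#' the genotype table's reference allele the dosage is flipped to
#' `2 - dosage`.
#'
#' @param geno a `genotype_table`.
#' @param summary data.frame with `id`, `beta`, `p` and optionally
#'   `effect_allele`.
#' @param thresholds p-value inclusion thresholds (default 50 log-spaced
#'   points from 5e-8 to 1; a dense arithmetic grid is available by
#'   passing it explicitly).
#' @return object of class `pgs_result`: `score` (threshold-averaged, named
#'   by subject), `per_threshold` matrix, `thresholds`, `n_snps` used per
#'   threshold.
#' @export
compute_pgs <- function(geno, summary,
                        thresholds = exp(seq(log(5e-8), log(1), length.out = 50))) {
  shared <- intersect(summary$id, geno$markers$id)
  if (!length(shared)) stop("no overlapping markers", call. = FALSE)
  s <- summary[match(shared, summary$id), , drop = FALSE]
  mi <- match(shared, geno$markers$id)
  D <- geno$dosages[, mi, drop = FALSE]
  if ("effect_allele" %in% names(s)) {
    flip <- s$effect_allele == geno$markers$ref[mi]
    if (any(flip)) D[, flip] <- 2 - D[, flip]
  }
  obs <- !is.na(D)
  D0 <- D; D0[!obs] <- 0
  per <- matrix(NA_real_, nrow(D), length(thresholds),
                dimnames = list(rownames(D), signif(thresholds, 3)))
  n_used <- integer(length(thresholds))
  for (ti in seq_along(thresholds)) {
    sel <- which(!is.na(s$p) & s$p <= thresholds[ti])
    n_used[ti] <- length(sel)
    if (!length(sel)) next
    num <- D0[, sel, drop = FALSE] %*% s$beta[sel]
    den <- 2 * rowSums(obs[, sel, drop = FALSE])
    per[, ti] <- ifelse(den > 0, num / den, NA_real_)
  }
  nonempty <- n_used > 0
  if (!any(nonempty)) stop("every threshold has an empty marker set", call. = FALSE)
  score <- rowMeans(per[, nonempty, drop = FALSE], na.rm = TRUE)
  structure(list(score = score, per_threshold = per, thresholds = thresholds,
                 n_snps = n_used),
            class = "pgs_result")
}

#' Greedy locus clumping by p-value, window and LD ceiling
#'
#' Repeatedly takes the smallest-p unclaimed SNP as an index and removes
#' unclaimed SNPs on the same chromosome within `window_kb` whose squared
#' dosage correlation with the index exceeds `r2_max`.
#'
#' @param summary data.frame with `id`, `chr`, `pos`, `p`.
#' @param geno a `genotype_table` sharing markers with `summary`.
#' @param window_kb physical window half-width in kb.
#' @param r2_max LD r-squared ceiling.
#' @return character vector of index SNP ids (in selection order).
#' @export
clump_locus <- function(summary, geno, window_kb = 250, r2_max = 0.1) {
  shared <- intersect(summary$id, geno$markers$id)
  s <- summary[match(shared, summary$id), , drop = FALSE]
  s <- s[!is.na(s$p), , drop = FALSE]
  if (!nrow(s)) return(character(0))
  D <- geno$dosages[, match(s$id, geno$markers$id), drop = FALSE]
  s <- s[order(s$p), , drop = FALSE]
  D <- D[, s$id, drop = FALSE]
  unclaimed <- rep(TRUE, nrow(s))
  index <- character(0)
  win <- window_kb * 1000
  for (i in seq_len(nrow(s))) {
    if (!unclaimed[i]) next
    index <- c(index, s$id[i])
    unclaimed[i] <- FALSE
    near <- which(unclaimed & s$chr == s$chr[i] & abs(s$pos - s$pos[i]) <= win)
    if (length(near)) {
      r <- suppressWarnings(stats::cor(D[, i], D[, near, drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r2 <- as.vector(r)^2
      r2[is.na(r2)] <- 0
      unclaimed[near[r2 > r2_max]] <- FALSE
    }
  }
  index
}
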