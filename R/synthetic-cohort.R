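#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set that defines the simulated study
#' conditions: a longitudinal adolescent discovery cohort with three latent
#' neurodevelopmental groups (continuously decreasing, slower-decreasing and
#' increasing regional GMV), genotypes with one causal SNP raising the odds of
#' the small "delayed development" group, methylation with one causal CpG on an
#' environment -> methylation -> GMV-slope path, a cross-sectional reference
#' cohort spanning childhood to early adulthood, and an adult cohort whose
#' outcomes are weakly correlated with a polygenic score.
#'
#' Group slope separations default to values whose implied per-ROI effect
#' sizes match the magnitudes reported for adolescent GMV-trajectory clusters
#' (d around 1 for the two large groups, d around 4 for the small increasing
#' group against the first); within-group slope dispersion is an assumption,
#' not an observed quantity.
#'
#' @param n_subjects number of adolescents drawn for the discovery cohort.
#' @param group_fractions latent group mixing proportions; must sum to 1.
#' @param visit_ages scheduled scan ages in years (first is baseline).
#' @param p_missing_visit probability that each non-baseline visit is missing;
#'   subjects left with fewer than two scans are dropped (the >=2 scan rule).
#' @param n_rois number of regions of interest.
#' @param baseline_means per-ROI baseline mean GMV (mm^3) at the baseline age;
#'   default is a graded range of plausible parcel volumes.
#' @param baseline_group_offsets 3-vector of group shifts applied to baseline
#'   GMV (mm^3), concentrated on the first 10 ROIs (profile 1 there, 0.3
#'   elsewhere) so that baseline classification has a known ROI support.
#' @param slope_means 3 x n_rois matrix of group mean GMV slopes (mm^3/yr);
#'   default encodes decreasing / slower-decreasing / increasing patterns.
#' @param slope_sd sd of the shared per-subject slope deviation (mm^3/yr).
#' @param slope_roi_sd sd of the independent per-subject, per-ROI slope
#'   deviation (mm^3/yr): regional rates vary within a person, not only by a
#'   shared scalar.
#' @param resid_sd residual scan noise sd (mm^3).
#' @param beta_sex,beta_hand additive covariate effects on GMV (mm^3).
#' @param site_effects per-site additive shifts on GMV (mm^3).
#' @param beta_icv GMV change per mm^3 of intracranial volume.
#' @param icv_meanlog,icv_sdlog lognormal parameters for ICV (mm^3).
#' @param n_snps,causal_snp_or,maf_range genotype block: marker count, the
#'   per-allele odds ratio by which the causal SNP raises group-3 membership,
#'   and the uniform range for minor-allele frequencies.
#' @param geno_missing_rate probability a dosage is missing.
#' @param n_cpgs methylation marker count.
#' @param cpg_env_a path coefficient from the environment score to the causal
#'   CpG on the logit scale.
#' @param cpg_group2_shift logit-scale hypermethylation of the causal CpG in
#'   group 2.
#' @param cpg_noise_sd logit-scale noise sd of CpG values.
#' @param cpg_slope_b effect (mm^3/yr per logit unit) of centered causal-CpG
#'   methylation on the subject GMV slope deviation (the mediation "b" path).
#' @param env_sd sd of the continuous environment exposure score.
#' @param n_ref_subjects,ref_age_range,ref_resid_sd cross-sectional reference
#'   cohort: size, age span, and scan noise.
#' @param n_adult,adult_outcome_rho adult cohort size and the true correlation
#'   between the polygenic score and each adult outcome.
#' @param seed master seed; every component draws from a named substream so
#'   adding one component does not perturb the others.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1500,
                       group_fractions = c(711, 765, 67) / 1543,
                       visit_ages = c(14, 19, 23),
                       p_missing_visit = 0.2,
                       n_rois = 44,
                       baseline_means = NULL,
                       baseline_group_offsets = c(0, 0, 0),
                       slope_means = NULL,
                       slope_sd = 10,
                       slope_roi_sd = 30,
                       resid_sd = 240,
                       beta_sex = -150,
                       site_effects = c(0, 80, -60, 40),
                       beta_hand = 20,
                       beta_icv = 0.002,
                       icv_meanlog = log(1.5e6),
                       icv_sdlog = 0.08,
                       n_snps = 2000,
                       causal_snp_or = 1.8,
                       maf_range = c(0.05, 0.5),
                       geno_missing_rate = 0.01,
                       n_cpgs = 2000,
                       cpg_env_a = 0.5,
                       cpg_group2_shift = 0.4,
                       cpg_noise_sd = 0.5,
                       cpg_slope_b = 6,
                       env_sd = 1,
                       n_ref_subjects = 2000,
                       ref_age_range = c(5, 25),
                       ref_resid_sd = 300,
                       n_adult = 10000,
                       adult_outcome_rho = 0.04,
                       seed = 1L) {
  if (abs(sum(group_fractions) - 1) > 1e-12)
    stop("group_fractions must sum to 1", call. = FALSE)
  if (any(group_fractions < 0))
    stop("group_fractions must be non-negative", call. = FALSE)
  if (n_subjects * min(group_fractions) < 2)
    stop("degenerate group: n_subjects * min(group_fractions) < 2", call. = FALSE)
  if (slope_sd < 0 || slope_roi_sd < 0 || resid_sd < 0 || ref_resid_sd < 0 ||
      cpg_noise_sd < 0)
    stop("noise sds must be non-negative", call. = FALSE)
  if (p_missing_visit < 0 || p_missing_visit > 1 || geno_missing_rate < 0 ||
      geno_missing_rate > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (causal_snp_or <= 0) stop("causal_snp_or must be > 0", call. = FALSE)
  if (abs(adult_outcome_rho) >= 1)
    stop("adult_outcome_rho must lie in (-1, 1)", call. = FALSE)
  if (ref_age_range[1] >= ref_age_range[2])
    stop("ref_age_range must be increasing", call. = FALSE)
  if (cpg_env_a != 0 && env_sd == 0)
    stop("cpg_env_a is nonzero but env_sd is 0: environment path undefined",
         call. = FALSE)

  phase <- if (n_rois > 1) (seq_len(n_rois) - 1) / (n_rois - 1) else 0
  if (is.null(baseline_means)) baseline_means <- 4000 + 250 * seq_len(n_rois)
  if (is.null(slope_means)) {
    slope_means <- rbind(
      g1 = -100 - 40 * sin(pi * phase),
      g2 = -60 - 30 * sin(pi * phase) - 10 * cos(2 * pi * phase),
      g3 = 60 + 20 * sin(2 * pi * phase)
    )
  }
  slope_means <- as.matrix(slope_means)
  if (!all(dim(slope_means) == c(3L, n_rois)))
    stop("slope_means must be a 3 x n_rois matrix", call. = FALSE)
  if (length(baseline_means) != n_rois)
    stop("baseline_means must have length n_rois", call. = FALSE)

  # ROI support of the baseline group offsets: strong on the first 10 parcels.
  offset_profile <- rep(0.3, n_rois)
  offset_profile[seq_len(min(10L, n_rois))] <- 1

  structure(list(
    n_subjects = as.integer(n_subjects), group_fractions = group_fractions,
    visit_ages = visit_ages, p_missing_visit = p_missing_visit,
    n_rois = as.integer(n_rois), baseline_means = baseline_means,
    baseline_group_offsets = baseline_group_offsets,
    offset_profile = offset_profile,
    slope_means = slope_means, slope_sd = slope_sd,
    slope_roi_sd = slope_roi_sd, resid_sd = resid_sd,
    beta_sex = beta_sex, site_effects = site_effects, beta_hand = beta_hand,
    beta_icv = beta_icv, icv_meanlog = icv_meanlog, icv_sdlog = icv_sdlog,
    n_snps = as.integer(n_snps), causal_snp_or = causal_snp_or,
    maf_range = maf_range, geno_missing_rate = geno_missing_rate,
    n_cpgs = as.integer(n_cpgs), cpg_env_a = cpg_env_a,
    cpg_group2_shift = cpg_group2_shift, cpg_noise_sd = cpg_noise_sd,
    cpg_slope_b = cpg_slope_b, env_sd = env_sd,
    n_ref_subjects = as.integer(n_ref_subjects), ref_age_range = ref_age_range,
    ref_resid_sd = ref_resid_sd, n_adult = as.integer(n_adult),
    adult_outcome_rho = adult_outcome_rho, seed = as.integer(seed)
  ), class = "sim_config")
}

roi_names <- function(n_rois) sprintf("roi%02d", seq_len(n_rois))

#' Simulate the full discovery cohort bundle
#'
#' Draws latent group labels from the configured mixing fractions and generates
#' every data component with known ground truth: longitudinal scans, genotypes,
#' methylation plus environment scores, and longitudinal outcomes. The GMV of
#' subject i in ROI r at age t is
#' `baseline_r + offset_{g(i),r} + (slope_{g(i),r} + b_i) * (t - t0) +
#'  covariates + noise`, with `b_i` a shared subject slope deviation (plus the
#' methylation "b" path when configured). Baseline scans are always present;
#' follow-ups are independently missing and subjects with fewer than two scans
#' are dropped, mirroring the >=2-scan inclusion rule.
#'
#' @param config a [sim_config()].
#' @return a `cohort_bundle` list: `subjects`, `scans`, `genotypes`,
#'   `methylation`, `environment`, `outcomes`, `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  ids <- sprintf("S%04d", seq_len(n))

  # group counts fixed at the configured mixing fractions (largest-remainder
  # rounding), randomly permuted: the fractions ARE the study condition.
  counts <- floor(config$group_fractions * n)
  rem <- config$group_fractions * n - counts
  short <- n - sum(counts)
  if (short > 0) {
    add <- order(-rem)[seq_len(short)]
    counts[add] <- counts[add] + 1L
  }
  subj <- with_seed(substream_seed(config$seed, "subjects"), {
    data.frame(
      subject = ids,
      true_group = sample(rep.int(1:3, counts)),
      sex = sample(c("F", "M"), n, replace = TRUE),
      site = sample(sprintf("site%d", seq_along(config$site_effects)), n, replace = TRUE),
      handedness = sample(c("L", "R"), n, replace = TRUE, prob = c(0.1, 0.9)),
      icv = stats::rlnorm(n, config$icv_meanlog, config$icv_sdlog),
      stringsAsFactors = FALSE
    )
  })

  env <- simulate_environment(config, n)
  meth <- simulate_methylation_env(config, subj$true_group, env)

  scans <- with_seed(substream_seed(config$seed, "scans"), {
    b <- stats::rnorm(n, 0, config$slope_sd)
    if (config$cpg_slope_b != 0) {
      m_centered <- meth$causal_logit - mean(meth$causal_logit)
      b <- b + config$cpg_slope_b * m_centered
    }
    # independent per-ROI slope deviations on top of the shared one
    E <- matrix(stats::rnorm(n * config$n_rois, 0, config$slope_roi_sd),
                n, config$n_rois)
    ages <- config$visit_ages
    present <- matrix(TRUE, n, length(ages))
    if (length(ages) > 1 && config$p_missing_visit > 0)
      present[, -1] <- matrix(stats::runif(n * (length(ages) - 1)) >= config$p_missing_visit,
                              n, length(ages) - 1)
    rows <- vector("list", length(ages))
    cov_shift <- config$beta_sex * (subj$sex == "M") +
      config$site_effects[match(subj$site, sprintf("site%d", seq_along(config$site_effects)))] +
      config$beta_hand * (subj$handedness == "R") +
      config$beta_icv * subj$icv
    g <- subj$true_group
    offs <- outer(config$baseline_group_offsets[g], config$offset_profile)
    # trajectories pivot at the mean scheduled visit age: groups then differ
    # at baseline too (the increasing group starts lowest), and the slope
    # deviations stay identifiable for subjects missing a follow-up.
    pivot <- mean(ages)
    for (v in seq_along(ages)) {
      t <- ages[v] - pivot
      mu <- matrix(config$baseline_means, n, config$n_rois, byrow = TRUE) + offs +
        (t(config$slope_means)[, g, drop = FALSE] |> t()) * t +
        (b + E) * t + cov_shift
      noise <- matrix(stats::rnorm(n * config$n_rois, 0, config$resid_sd),
                      n, config$n_rois)
      gmv <- mu + noise
      colnames(gmv) <- roi_names(config$n_rois)
      rows[[v]] <- data.frame(subject = ids, age = ages[v], visit = v,
                              sex = subj$sex, site = subj$site,
                              handedness = subj$handedness, icv = subj$icv,
                              stringsAsFactors = FALSE)[present[, v], , drop = FALSE]
      rows[[v]] <- cbind(rows[[v]], as.data.frame(gmv[present[, v], , drop = FALSE]))
    }
    list(tab = do.call(rbind, rows), b = b)
  })

  scan_tab <- scans$tab[order(scan_tab_key <- paste(scans$tab$subject,
                                                    sprintf("%06.2f", scans$tab$age))), ]
  rownames(scan_tab) <- NULL
  keep <- names(which(table(scan_tab$subject) >= 2))
  dropped <- setdiff(ids, keep)
  scan_tab <- scan_tab[scan_tab$subject %in% keep, ]
  subj <- subj[subj$subject %in% keep, ]
  rownames(subj) <- NULL

  geno <- simulate_genotypes(config, stats::setNames(subj$true_group, subj$subject))

  outcomes <- with_seed(substream_seed(config$seed, "outcomes"), {
    g <- subj$true_group
    nk <- nrow(subj)
    base_tot <- rowSums(scan_tab[scan_tab$visit == 1,
                                 roi_names(config$n_rois)][match(subj$subject,
                                   scan_tab$subject[scan_tab$visit == 1]), , drop = FALSE])
    zt <- as.vector(scale(base_tot))
    mk <- function(g2eff, g3eff) {
      0.25 * zt + g2eff * (g == 2) + g3eff * (g == 3) + stats::rnorm(nk)
    }
    rbind(
      data.frame(subject = subj$subject, visit = "baseline",
                 wm = mk(-0.35, -1.0), cgt = mk(-0.30, -0.9), sst = mk(-0.25, -0.8),
                 stringsAsFactors = FALSE),
      data.frame(subject = subj$subject, visit = "followup",
                 wm = mk(-0.45, -0.15), cgt = mk(-0.45, -0.10), sst = mk(-0.40, -0.10),
                 stringsAsFactors = FALSE)
    )
  })

  meth$table <- meth$table[rownames(meth$table) %in% keep, , drop = FALSE]
  env_tab <- data.frame(subject = ids, env = env, stringsAsFactors = FALSE)
  env_tab <- env_tab[env_tab$subject %in% keep, ]
  rownames(env_tab) <- NULL

  structure(list(
    subjects = subj,
    scans = scan_tab,
    genotypes = geno,
    methylation = list(values = meth$table, markers = meth$markers),
    environment = env_tab,
    outcomes = outcomes,
    truth = list(
      group = stats::setNames(subj$true_group, subj$subject),
      slope_deviation = stats::setNames(scans$b, ids)[keep],
      causal_snp = geno$markers$id[geno$markers$causal],
      causal_cpg = meth$markers$id[meth$markers$causal],
      dropped_subjects = dropped,
      config = config
    )
  ), class = "cohort_bundle")
}

simulate_environment <- function(config, n) {
  with_seed(substream_seed(config$seed, "environment"),
            stats::rnorm(n, 0, config$env_sd))
}

#' Simulate genotype dosages with one causal SNP
#'
#' Null SNPs are drawn in Hardy-Weinberg proportions with uniform minor-allele
#' frequencies. The causal SNP is sampled retrospectively given the group
#' label: in group 3 the genotype probabilities are tilted by
#' `causal_snp_or^dosage`, so its per-allele log-odds for group-3 membership is
#' `log(causal_snp_or)`. Markers near the causal SNP (within 250 kb on the
#' synthetic map) partially copy its genotype so that locus clumping has
#' correlated neighbours to remove.
#'
#' @param config a [sim_config()].
#' @param true_group named integer vector of group labels (names = subjects).
#' @return a `genotype_table` list: `dosages` (subjects x SNPs matrix, may
#'   contain NA) and `markers` (id, chr, pos, ref, alt, maf, causal).
#' @export
simulate_genotypes <- function(config, true_group) {
  stopifnot(!is.null(names(true_group)))
  n <- length(true_group)
  p <- config$n_snps
  with_seed(substream_seed(config$seed, "genotypes"), {
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    causal_idx <- max(1L, p %/% 2L)
    # synthetic map: a 250 kb cluster of up to 30 SNPs around the causal one
    # on chromosome 6; everything else spread over chromosomes 1-22.
    chr <- sample(1:22, p, replace = TRUE)
    pos <- sample.int(2e8, p, replace = TRUE)
    cluster <- causal_idx + setdiff(seq(-15L, 15L), 0L)
    cluster <- cluster[cluster >= 1 & cluster <= p]
    chr[c(causal_idx, cluster)] <- 6L
    pos[causal_idx] <- 126400000L
    pos[cluster] <- 126400000L + as.integer(round(stats::runif(length(cluster), -240000, 240000)))
    dup <- duplicated(paste(chr, pos))
    pos[dup] <- pos[dup] + seq_len(sum(dup))

    D <- matrix(0L, n, p, dimnames = list(names(true_group), sprintf("rs%05d", seq_len(p))))
    for (j in seq_len(p)) D[, j] <- stats::rbinom(n, 2L, maf[j])
    # causal SNP: retrospective sampling given the group label
    hwe <- c((1 - maf[causal_idx])^2, 2 * maf[causal_idx] * (1 - maf[causal_idx]),
             maf[causal_idx]^2)
    or <- config$causal_snp_or
    w3 <- hwe * or^(0:2)
    g3 <- true_group == 3
    D[!g3, causal_idx] <- sample(0:2, sum(!g3), replace = TRUE, prob = hwe)
    if (any(g3)) D[g3, causal_idx] <- sample(0:2, sum(g3), replace = TRUE, prob = w3 / sum(w3))
    # block-level LD: cluster SNPs copy the causal genotype with prob 0.7
    for (j in cluster) {
      copy <- stats::runif(n) < 0.7
      D[copy, j] <- D[copy, causal_idx]
    }
    Dn <- matrix(as.numeric(D), n, p, dimnames = dimnames(D))
    if (config$geno_missing_rate > 0)
      Dn[stats::runif(n * p) < config$geno_missing_rate] <- NA_real_
    markers <- data.frame(
      id = colnames(Dn), chr = chr, pos = pos, ref = "A", alt = "G",
      maf = maf, causal = seq_len(p) == causal_idx, stringsAsFactors = FALSE
    )
    structure(list(dosages = Dn, markers = markers), class = "genotype_table")
  })
}

#' Simulate methylation beta values and the environment exposure
#'
#' One causal CpG follows `logit(beta) = mu + a * env + shift * [group == 2] +
#' noise`; all other CpGs are independent logit-normal noise, so every value
#' lies strictly inside (0, 1).
#'
#' @param config a [sim_config()].
#' @param true_group integer group labels.
#' @param env optional pre-drawn environment scores (drawn from the
#'   environment substream when NULL).
#' @return list with `table` (subjects x CpGs beta values), `markers`
#'   (id, chr, pos, causal), `causal_logit`, and `env`.
#' @export
simulate_methylation_env <- function(config, true_group, env = NULL) {
  n <- length(true_group)
  if (is.null(env)) env <- simulate_environment(config, n)
  with_seed(substream_seed(config$seed, "methylation"), {
    p <- config$n_cpgs
    mu <- stats::rnorm(p, 0, 0.8)
    causal_idx <- max(1L, p %/% 4L)
    L <- matrix(stats::rnorm(n * p, 0, config$cpg_noise_sd), n, p)
    L <- sweep(L, 2, mu, "+")
    L[, causal_idx] <- mu[causal_idx] + config$cpg_env_a * env +
      config$cpg_group2_shift * (true_group == 2) +
      stats::rnorm(n, 0, config$cpg_noise_sd)
    B <- stats::plogis(L)
    ids <- sprintf("cg%07d", seq_len(p))
    dimnames(B) <- list(if (!is.null(names(true_group))) names(true_group)
                        else sprintf("S%04d", seq_len(n)), ids)
    markers <- data.frame(id = ids, chr = sample(1:22, p, replace = TRUE),
                          pos = sample.int(2e8, p, replace = TRUE),
                          causal = seq_len(p) == causal_idx,
                          stringsAsFactors = FALSE)
    markers$chr[causal_idx] <- 2L
    list(table = B, markers = markers, causal_logit = L[, causal_idx], env = env)
  })
}

#' Simulate the cross-sectional reference cohort
#'
#' One scan per subject at an age uniform over the reference range; each ROI
#' follows a known quadratic-in-age mean curve anchored so that its value at
#' the discovery baseline age equals the configured baseline mean. Two study
#' labels with a pure intercept offset exercise the study adjustment.
#'
#' @param config a [sim_config()].
#' @return a scan table (one row per subject) with `study`, `total_gmv` and
#'   attribute `generating` holding the true quadratic coefficients.
#' @export
simulate_reference <- function(config) {
  with_seed(substream_seed(config$seed, "reference"), {
    n <- config$n_ref_subjects
    phase <- if (config$n_rois > 1) (seq_len(config$n_rois) - 1) / (config$n_rois - 1) else 0
    peak_age <- 10 + 4 * phase
    curv <- 3 + 2 * phase
    height <- config$baseline_means + curv * (config$visit_ages[1] - peak_age)^2
    age <- stats::runif(n, config$ref_age_range[1], config$ref_age_range[2])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    study <- rep(c("ref1", "ref2"), length.out = n)
    icv <- stats::rlnorm(n, config$icv_meanlog, config$icv_sdlog)
    G <- matrix(0, n, config$n_rois, dimnames = list(NULL, roi_names(config$n_rois)))
    for (r in seq_len(config$n_rois))
      G[, r] <- height[r] - curv[r] * (age - peak_age[r])^2 +
        stats::rnorm(n, 0, config$ref_resid_sd)
    G <- G + 100 * (study == "ref2")
    out <- data.frame(subject = sprintf("R%05d", seq_len(n)), age = age,
                      sex = sex, study = study, icv = icv,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(G))
    out$total_gmv <- rowSums(G)
    attr(out, "generating") <- list(peak_age = peak_age, curv = curv,
                                    height = height, study2_offset = 100)
    out
  })
}

#' Simulate an independent adult cohort with PGS-correlated outcomes
#'
#' Adult genotypes are drawn independently (Hardy-Weinberg at the marker MAFs
#' in `snp_weights`); each outcome equals `rho * z(PGS) + sqrt(1 - rho^2) *
#' noise`, where the PGS is the weighted allele-dosage sum over the supplied
#' markers.
#'
#' @param config a [sim_config()].
#' @param snp_weights data.frame with columns `id`, `beta`, `maf` (per-marker
#'   effect sizes to embed in the outcomes).
#' @param outcome_names names of the generated outcome columns.
#' @return list with `genotypes` (a `genotype_table`) and `outcomes`.
#' @export
simulate_adult_cohort <- function(config, snp_weights,
                                  outcome_names = c("income", "fluid_iq", "neuroticism")) {
  stopifnot(all(c("id", "beta", "maf") %in% names(snp_weights)))
  with_seed(substream_seed(config$seed, "adult"), {
    n <- config$n_adult
    p <- nrow(snp_weights)
    D <- matrix(0, n, p, dimnames = list(sprintf("A%06d", seq_len(n)), snp_weights$id))
    for (j in seq_len(p)) D[, j] <- stats::rbinom(n, 2L, snp_weights$maf[j])
    score <- as.vector(D %*% snp_weights$beta)
    z <- if (stats::sd(score) > 0) (score - mean(score)) / stats::sd(score) else score * 0
    rho <- config$adult_outcome_rho
    out <- data.frame(subject = rownames(D), stringsAsFactors = FALSE)
    for (nm in outcome_names)
      out[[nm]] <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    markers <- data.frame(id = snp_weights$id,
                          chr = snp_weights$chr %||% 1L,
                          pos = snp_weights$pos %||% seq_len(p),
                          ref = "A", alt = "G", maf = snp_weights$maf,
                          causal = FALSE, stringsAsFactors = FALSE)
    list(genotypes = structure(list(dosages = D, markers = markers),
                               class = "genotype_table"),
         outcomes = out)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write every cohort artifact as plain-text tables
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(bundle$subjects, "subjects.csv")
  w(bundle$scans, "scans.csv")
  w(cbind(subject = rownames(bundle$genotypes$dosages),
          as.data.frame(bundle$genotypes$dosages)), "genotypes.csv")
  utils::write.table(bundle$genotypes$markers, file.path(dir, "snps.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  w(cbind(subject = rownames(bundle$methylation$values),
          as.data.frame(bundle$methylation$values)), "methylation.csv")
  utils::write.table(bundle$methylation$markers, file.path(dir, "cpgs.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  w(bundle$environment, "environment.csv")
  w(bundle$outcomes, "outcomes.csv")
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
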