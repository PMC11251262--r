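#' Pipeline configuration
#'
#' Collects the tunables of the end-to-end workflow. Either `simulate` (a
#' [sim_config()]) or `paths` (a named list for [load_tables()]) supplies the
#' input cohort.
#'
#' @param simulate a [sim_config()] (default: the standard synthetic cohort).
#' @param paths named list of input files (alternative to `simulate`).
#' @param out_dir run directory for artifacts.
#' @param seed global seed (overrides the simulate seed so one integer drives
#'   the whole run).
#' @param stages character vector of stage toggles; subset of
#'   `c("cluster", "characterize", "curves", "proxy", "genetics",
#'   "methylation", "mediation", "adult")`.
#' @param k_iqr outlier rule IQR multiplier.
#' @param variance_target,k_range,min_frac,restarts clustering tunables.
#' @param perm_B,restarts_perm permutation-test tunables.
#' @param contrast_pairs list of group pairs for ROI contrasts.
#' @param icv_basis_df,gmv_basis_df peak-estimation spline dimensions.
#' @param n_geno_pcs genotype principal components used as GWAS covariates.
#' @param pgs_thresholds PGS inclusion thresholds.
#' @param clump_window_kb,clump_r2 clumping tunables.
#' @param mediation_B mediation bootstrap resamples.
#' @param delta inferiority margin.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), paths = NULL,
                            out_dir = tempfile("gmvtraj_run_"), seed = 7L,
                            stages = c("cluster", "characterize", "curves",
                                       "proxy", "genetics", "methylation",
                                       "mediation", "adult"),
                            k_iqr = 4, variance_target = 0.80, k_range = 2:8,
                            min_frac = 0.04, restarts = 50, perm_B = 199,
                            restarts_perm = 10,
                            contrast_pairs = list(c(3, 1), c(2, 1)),
                            icv_basis_df = 5, gmv_basis_df = 12,
                            n_geno_pcs = 10,
                            pgs_thresholds = exp(seq(log(5e-8), log(1),
                                                     length.out = 50)),
                            clump_window_kb = 250, clump_r2 = 0.1,
                            mediation_B = 1000, delta = 0.05) {
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "sim_config"))
    simulate$seed <- as.integer(seed)
  }
  cfg <- list(simulate = simulate, paths = paths, out_dir = out_dir,
              seed = as.integer(seed), stages = stages, k_iqr = k_iqr,
              variance_target = variance_target, k_range = k_range,
              min_frac = min_frac, restarts = restarts, perm_B = perm_B,
              restarts_perm = restarts_perm, contrast_pairs = contrast_pairs,
              icv_basis_df = icv_basis_df, gmv_basis_df = gmv_basis_df,
              n_geno_pcs = n_geno_pcs, pgs_thresholds = pgs_thresholds,
              clump_window_kb = clump_window_kb, clump_r2 = clump_r2,
              mediation_B = mediation_B, delta = delta)
  class(cfg) <- "pipeline_config"
  cfg
}

# FNV-1a-style hash of the serialized configuration (hex string).
config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL  # hash the scientific content, not the artifact path
  s <- paste(deparse(cfg), collapse = "\n")
  h <- 2166136261
  for (c in utf8ToInt(s)) h <- (bitwXor(as.integer(h %% 2^31), c) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the end-to-end workflow
#'
#' Executes simulate (or load) -> outlier filter -> trajectories -> PCA /
#' clustering / permutation -> group characterization -> growth curves and
#' peaks -> proxy loadings and score -> genotype QC / GWAS / EWAS / PGS /
#' clumping -> mediation -> inferiority, writing every stage artifact plus a
#' run manifest (config hash, seed, versions, per-stage wall time) and a
#' structured log under the run directory. Stages absent from
#' `config$stages`, and stages whose dependencies were skipped, are logged
#' and skipped.
#'
#' @param config a [pipeline_config()].
#' @return the run directory, invisibly; the returned object carries the
#'   in-memory stage results as attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  timings <- list()
  res <- list()
  logf <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, enabled, deps = character(0), expr) {
    if (!enabled) { logf("stage %s: skipped (toggle off)", name); return(NULL) }
    missing_dep <- deps[!deps %in% names(res)]
    if (length(missing_dep)) {
      logf("stage %s: skipped (missing dependency: %s)", name,
           paste(missing_dep, collapse = ", "))
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("stage %s: FAILED: %s", name,
                                      conditionMessage(e))),
                 file.path(config$out_dir, "run.log"))
      file.create(file.path(config$out_dir, paste0(name, ".failed")))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    logf("stage %s: done in %.2f s", name, timings[[name]])
    out
  }
  on <- function(s) s %in% config$stages
  wcsv <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f),
                                          row.names = FALSE)
  wtsv <- function(x, f) utils::write.table(x, file.path(config$out_dir, f),
                                            sep = "\t", row.names = FALSE,
                                            quote = FALSE)
  wjson <- function(x, f) jsonlite::write_json(x, file.path(config$out_dir, f),
                                               auto_unbox = TRUE, digits = NA,
                                               pretty = TRUE)

  res$bundle <- stage("input", TRUE, character(0), {
    if (!is.null(config$simulate)) simulate_cohort(config$simulate)
    else load_tables(config$paths)
  })
  bundle <- res$bundle
  covs <- bundle$subjects[, c("subject", "sex", "site", "handedness", "icv")]

  res$outliers <- stage("outliers", TRUE, "bundle", {
    fl <- flag_gmv_outliers(bundle$scans, k_iqr = config$k_iqr)
    if (length(fl$subjects)) {
      bundle$scans <- bundle$scans[!bundle$scans$subject %in% fl$subjects, ]
      bundle$subjects <- bundle$subjects[!bundle$subjects$subject %in% fl$subjects, ]
    }
    wcsv(fl$flags, "outliers.csv")
    fl
  })

  res$traj <- stage("trajectories", TRUE, "outliers", {
    tm <- build_trajectory_matrix(bundle$scans)
    wcsv(cbind(subject = rownames(tm), as.data.frame(unclass(tm))),
         "trajectories.csv")
    wjson(attr(tm, "fits"), "fits.json")
    tm
  })

  res$cluster <- stage("cluster", on("cluster"), "traj", {
    pr <- standardize_project(res$traj, config$variance_target)
    sel <- select_k(pr$scores, k_range = config$k_range,
                    min_frac = config$min_frac, restarts = config$restarts,
                    seed = substream_seed(config$seed, "select_k"))
    # relabel clusters by descending size (largest = 1), for stable reporting
    ord <- order(-sel$solution$sizes)
    relab <- match(sel$solution$labels, ord)
    perm <- permutation_validity(res$traj, sel$k, B = config$perm_B,
                                 seed = substream_seed(config$seed, "perm"),
                                 restarts_perm = config$restarts_perm,
                                 variance_target = config$variance_target,
                                 observed_ratio = sel$solution$ratio)
    wcsv(data.frame(subject = rownames(pr$scores), label = relab), "clusters.csv")
    wjson(list(ratios = pr$model$ratios, m_selected = pr$model$m_selected,
               variance_target = config$variance_target), "pca.json")
    wjson(list(observed = perm$observed, p = perm$p, B = perm$B,
               seed = perm$seed), "permutation.json")
    list(pca = pr, k = sel$k, solution = sel$solution,
         labels = stats::setNames(relab, rownames(pr$scores)),
         diagnostics = sel$diagnostics, permutation = perm)
  })

  res$characterize <- stage("characterize", on("characterize"), "cluster", {
    labels <- res$cluster$labels
    cov_traj <- covs[match(rownames(res$traj), covs$subject),
                     c("sex", "site", "handedness", "icv")]
    present <- as.integer(names(which(table(labels) >= 2)))
    pairs <- Filter(function(p) all(p %in% present), config$contrast_pairs)
    if (!length(pairs)) {
      logf("characterize: no configured contrast pair has both clusters")
      NULL
    } else {
      tabs <- lapply(pairs, function(pair) {
        ct <- roi_contrasts(res$traj, labels[rownames(res$traj)], pair,
                            covariates = cov_traj)
        cbind(pair = paste(pair, collapse = "v"), ct$table)
      })
      roi_tab <- do.call(rbind, tabs)
      out_tabs <- lapply(pairs, function(pair) {
        oc <- outcome_contrasts(bundle$outcomes, labels, pair,
                                covariates = covs[, c("subject", "sex",
                                                      "handedness", "icv")],
                                baseline_adjust = TRUE)
        if (!is.null(oc)) cbind(pair = paste(pair, collapse = "v"), oc)
      })
      out_tab <- do.call(rbind, out_tabs)
      wtsv(roi_tab, "contrasts.tsv")
      if (!is.null(out_tab)) wtsv(out_tab, "outcome_contrasts.tsv")
      list(roi = roi_tab, outcomes = out_tab)
    }
  })

  res$curves <- stage("curves", on("curves"), "cluster", {
    ref <- if (!is.null(config$simulate)) simulate_reference(config$simulate)
           else bundle$reference
    refcurve <- fit_reference_curve(ref)
    sc <- bundle$scans
    sc$total_gmv <- rowSums(sc[, grep("^roi", names(sc)), drop = FALSE])
    gc <- fit_group_deviation_curves(sc, res$cluster$labels, refcurve)
    rate_ages <- c(5, 10, 15, 20, 25)
    rate_ages <- rate_ages[rate_ages >= gc$domain[1] & rate_ages <= gc$domain[2]]
    rates <- growth_rate(gc, rate_ages)
    pk <- estimate_peak(sc, ref, res$cluster$labels,
                        icv_basis_df = config$icv_basis_df,
                        gmv_basis_df = config$gmv_basis_df)
    wcsv(gc$curves, "curves.csv")
    wcsv(rates, "growth_rates.csv")
    wjson(list(peaks = pk$peaks), "peaks.json")
    wcsv(pk$subject_peaks, "subject_peaks.csv")
    list(reference = refcurve, curves = gc, rates = rates, peaks = pk)
  })

  res$proxy <- stage("proxy", on("proxy"), "cluster", {
    base <- bundle$scans[order(bundle$scans$subject, bundle$scans$age), ]
    base <- base[!duplicated(base$subject), ]  # earliest scan = baseline
    # constant covariates (e.g. age when every baseline is scheduled at the
    # same visit age) carry no information and break the design rank
    drop_const <- function(df) {
      keep <- vapply(names(df), function(nm)
        nm == "subject" || length(unique(df[[nm]])) > 1, TRUE)
      df[, keep, drop = FALSE]
    }
    base_gmv <- base[, c("subject", grep("^roi", names(base), value = TRUE))]
    cv <- cbind(covs, age = base$age[match(covs$subject, base$subject)])
    # the "delayed development" case class is the smallest cluster
    # (label k after size ordering), contrasted against all others
    kk <- res$cluster$k
    lv <- fit_loadings(base_gmv, res$cluster$labels,
                       contrast = list(case = kk, control = seq_len(kk - 1)),
                       covariates = drop_const(cv[, c("subject", "age", "sex",
                                                      "handedness", "site")]))
    px <- reweight_gmv(base_gmv, lv)
    base_out <- bundle$outcomes[bundle$outcomes$visit == "baseline",
                                setdiff(names(bundle$outcomes), "visit")]
    val <- validate_proxy(px, base_out,
                          covariates = drop_const(cv[, c("subject", "age",
                                                         "sex")]))
    wtsv(data.frame(roi = names(lv$loadings), coefficient = lv$loadings,
                    selected = names(lv$loadings) %in% lv$selected),
         "loadings.tsv")
    wcsv(px, "proxy.csv")
    wtsv(val, "proxy_validation.tsv")
    list(loadings = lv, score = px, validation = val)
  })

  res$genetics <- stage("genetics", on("genetics") && !is.null(bundle$genotypes),
                        "proxy", {
    qc <- qc_genotypes(bundle$genotypes)
    # genotype PCs as ancestry covariates (columns mean-imputed for the SVD)
    D <- qc$genotypes$dosages
    Dm <- apply(D, 2, function(d) { d[is.na(d)] <- mean(d, na.rm = TRUE); d })
    Dm <- Dm[, apply(Dm, 2, stats::sd) > 0, drop = FALSE]
    npc <- min(config$n_geno_pcs, nrow(Dm) - 1, ncol(Dm))
    # left singular vectors via the subject-by-subject Gram matrix, which is
    # far smaller than the marker dimension
    Z <- scale(Dm)
    ei <- eigen(tcrossprod(Z), symmetric = TRUE)
    pcs <- ei$vectors[, seq_len(npc), drop = FALSE]
    colnames(pcs) <- paste0("PC", seq_len(npc))
    gcov <- cbind(covs[match(rownames(D), covs$subject), c("subject", "sex", "site")],
                  as.data.frame(pcs))
    gw <- gwas_scan(res$proxy$score, qc$genotypes, covariates = gcov)
    wtsv(gw, "gwas.tsv")
    if (!is.null(qc$report)) wtsv(qc$report, "genotype_qc.tsv")
    idx <- clump_locus(gw, qc$genotypes, window_kb = config$clump_window_kb,
                       r2_max = config$clump_r2)
    wjson(list(index_snps = idx), "clump.json")
    summ <- gw[!is.na(gw$p), c("id", "chr", "pos", "beta", "p")]
    pgs <- compute_pgs(qc$genotypes, summ, thresholds = config$pgs_thresholds)
    wcsv(data.frame(subject = names(pgs$score), score = pgs$score), "pgs.csv")
    list(qc = qc, gwas = gw, clump = idx, pgs = pgs, summary = summ)
  })

  res$ewas <- stage("ewas", on("methylation") && !is.null(bundle$methylation),
                    "cluster", {
    ew <- ewas_scan(res$cluster$labels, pair = c(2, 1), bundle$methylation,
                    covariates = covs[, c("subject", "sex")],
                    seed = substream_seed(config$seed, "ewas"))
    wtsv(ew, "ewas.tsv")
    ew
  })

  res$mediation <- stage("mediation", on("mediation"),
                         c("ewas", "curves"), {
    ew <- res$ewas
    top_cpg <- ew$id[which.min(ew$p)]
    labels <- res$cluster$labels
    g12 <- names(labels)[labels %in% c(1, 2)]
    sub <- intersect(intersect(g12, bundle$environment$subject),
                     rownames(bundle$methylation$values))
    sub <- intersect(sub, res$curves$peaks$subject_peaks$subject)
    med <- fit_mediation(
      X = bundle$environment$env[match(sub, bundle$environment$subject)],
      M = bundle$methylation$values[sub, top_cpg],
      Y = res$curves$peaks$subject_peaks$peak_gmv[
        match(sub, res$curves$peaks$subject_peaks$subject)],
      covariates = covs[match(sub, covs$subject), c("sex", "icv")],
      B = config$mediation_B,
      seed = substream_seed(config$seed, "mediation"))
    wtsv(data.frame(exposure = "env", mediator = top_cpg,
                    t(med$estimates), se_indirect = med$se[["indirect"]],
                    ci_lower = med$ci["indirect", "lower"],
                    ci_upper = med$ci["indirect", "upper"],
                    p_indirect = med$p[["indirect"]]),
         "mediation.tsv")
    med
  })

  res$adult <- stage("adult", on("adult"), "genetics", {
    summ <- res$genetics$summary
    weights <- merge(summ, res$genetics$qc$genotypes$markers[, c("id", "maf")],
                     by = "id")
    adult <- simulate_adult_cohort(config$simulate, weights)
    apgs <- compute_pgs(adult$genotypes, summ, thresholds = config$pgs_thresholds)
    ocols <- setdiff(names(adult$outcomes), "subject")
    inf <- lapply(ocols, function(oc) {
      it <- inferiority_test(apgs$score[adult$outcomes$subject],
                             adult$outcomes[[oc]], delta = config$delta)
      data.frame(outcome = oc, r = it$r, n = it$n,
                 p_inferiority = it$p_inferiority, conclusion = it$conclusion,
                 stringsAsFactors = FALSE)
    })
    inf_tab <- do.call(rbind, inf)
    wtsv(inf_tab, "inferiority.tsv")
    list(pgs = apgs, outcomes = adult$outcomes, inferiority = inf_tab)
  })

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gmvtraj")),
    r_version = R.version.string,
    stages_run = names(timings),
    stage_seconds = timings
  )
  wjson(manifest, "run_manifest.json")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  out <- config$out_dir
  attr(out, "results") <- res
  invisible(out)
}

#' Load and validate cohort tables from files
#'
#' Reads the documented CSV schemas (scans, subjects, optional genotypes /
#' methylation / environment / outcomes tables) with precise validation
#' errors; genotype dosages may alternatively come from a VCF with DS (or GT)
#' fields. Empty optional components are returned as NULL so dependent
#' pipeline stages auto-skip.
#'
#' @param paths named list: `scans`, `subjects`, and optionally `genotypes`
#'   + `snps`, `vcf`, `methylation` + `cpgs`, `environment`, `outcomes`,
#'   `reference`.
#' @param age_range plausible age range for validation.
#' @return a `cohort_bundle`-shaped list.
#' @export
load_tables <- function(paths, age_range = c(4, 30)) {
  need <- function(f) {
    if (is.null(f) || !file.exists(f)) stop("missing input file: ", f, call. = FALSE)
    f
  }
  scans <- utils::read.csv(need(paths$scans), stringsAsFactors = FALSE)
  req <- c("subject", "age", "sex", "site", "handedness", "icv")
  miss <- setdiff(req, names(scans))
  if (length(miss))
    stop("scans table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  dup <- duplicated(scans[, c("subject", "age")])
  if (any(dup))
    stop("duplicated (subject, age) rows in scans: rows ",
         paste(utils::head(which(dup), 10), collapse = ", "), call. = FALSE)
  rois <- grep("^roi", names(scans), value = TRUE)
  if (!length(rois)) stop("scans table has no ROI columns (prefix 'roi')", call. = FALSE)
  bad_age <- scans$age < age_range[1] | scans$age > age_range[2]
  if (any(bad_age))
    stop("implausible ages in scans: rows ",
         paste(utils::head(which(bad_age), 10), collapse = ", "), call. = FALSE)
  bad_gmv <- which(as.matrix(scans[, rois]) <= 0)
  if (length(bad_gmv))
    stop("non-positive GMV values in scans (", length(bad_gmv), " cells)",
         call. = FALSE)
  subjects <- utils::read.csv(need(paths$subjects), stringsAsFactors = FALSE)
  orphan <- setdiff(scans$subject, subjects$subject)
  if (length(orphan))
    stop("scan subjects absent from subjects table: ",
         paste(utils::head(orphan, 10), collapse = ", "), call. = FALSE)

  geno <- NULL
  if (!is.null(paths$vcf)) {
    geno <- read_vcf_dosages(need(paths$vcf))
  } else if (!is.null(paths$genotypes)) {
    gt <- utils::read.csv(need(paths$genotypes), stringsAsFactors = FALSE,
                          check.names = FALSE)
    D <- as.matrix(gt[, -1, drop = FALSE])
    rownames(D) <- gt[[1]]
    markers <- utils::read.delim(need(paths$snps), stringsAsFactors = FALSE)
    if (!all(colnames(D) == markers$id))
      stop("genotype columns and snps metadata ids disagree", call. = FALSE)
    if (any(D < 0 | D > 2, na.rm = TRUE))
      stop("dosages outside [0, 2]", call. = FALSE)
    geno <- structure(list(dosages = D, markers = markers),
                      class = "genotype_table")
  }
  meth <- NULL
  if (!is.null(paths$methylation) && file.exists(paths$methylation) &&
      file.size(paths$methylation) > 0) {
    mt <- utils::read.csv(paths$methylation, stringsAsFactors = FALSE,
                          check.names = FALSE)
    M <- as.matrix(mt[, -1, drop = FALSE])
    rownames(M) <- mt[[1]]
    if (any(M < 0 | M > 1, na.rm = TRUE))
      stop("methylation beta values outside [0, 1]", call. = FALSE)
    meth <- list(values = M,
                 markers = utils::read.delim(need(paths$cpgs),
                                             stringsAsFactors = FALSE))
  }
  env <- if (!is.null(paths$environment))
    utils::read.csv(need(paths$environment), stringsAsFactors = FALSE)
  outc <- if (!is.null(paths$outcomes))
    utils::read.csv(need(paths$outcomes), stringsAsFactors = FALSE)
  ref <- if (!is.null(paths$reference))
    utils::read.csv(need(paths$reference), stringsAsFactors = FALSE)
  structure(list(subjects = subjects, scans = scans, genotypes = geno,
                 methylation = meth, environment = env, outcomes = outc,
                 reference = ref, truth = NULL),
            class = "cohort_bundle")
}

#' Read biallelic dosages from a VCF file
#'
#' Uses the DS FORMAT field when present, falling back to the GT allele
#' count. Only biallelic records are supported.
#'
#' @param path VCF file (plain text or gzipped).
#' @return a `genotype_table`.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) stop("multiallelic VCF records are not supported", call. = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]))
    })
  }
  D <- t(ds)
  markers <- data.frame(id = fix[, "ID"], chr = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                        alt = fix[, "ALT"], stringsAsFactors = FALSE)
  colnames(D) <- markers$id
  structure(list(dosages = D, markers = markers), class = "genotype_table")
}

#' Write dosages as a minimal VCF 4.2 file
#'
#' Emits one biallelic record per marker with a DS FORMAT field, suitable for
#' round-tripping through [read_vcf_dosages()].
#'
#' @param geno a `genotype_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf_dosages <- function(geno, path) {
  D <- geno$dosages
  m <- geno$markers
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(D)), collapse = "\t"))
  body <- vapply(seq_len(ncol(D)), function(j) {
    ds <- ifelse(is.na(D[, j]), ".", format(D[, j], trim = TRUE, digits = 10))
    paste(c(m$chr[j], m$pos[j], m$id[j], m$ref[j], m$alt[j], ".", "PASS", ".",
            "DS", ds), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}
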