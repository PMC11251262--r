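#' Flag subjects with extreme regional GMV values
#'
#' A subject is flagged if any ROI value at any visit lies outside
#' `[Q1 - k*IQR, Q3 + k*IQR]`, with quartiles computed per ROI over all
#' observations. With a zero IQR the bounds collapse to the constant, so only
#' values differing from it are flagged; an infinite `k_iqr` flags nothing.
#'
#' @param scans scan table with one row per (subject, visit) and ROI columns.
#' @param k_iqr multiplier on the interquartile range (default 4).
#' @param rois ROI column names (default: columns matching `^roi`).
#' @return list with `subjects` (ids to exclude) and `flags`
#'   (subject, roi, age, value rows).
#' @export
flag_gmv_outliers <- function(scans, k_iqr = 4, rois = grep("^roi", names(scans), value = TRUE)) {
  if (nrow(scans) == 0) stop("empty scan table", call. = FALSE)
  if (length(unique(scans$subject)) < 8)
    stop("need >= 8 subjects for quartile stability", call. = FALSE)
  flags <- list()
  for (r in rois) {
    x <- scans[[r]]
    if (is.infinite(k_iqr)) next
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[2] - q[1]
    bad <- x < q[1] - k_iqr * iqr | x > q[2] + k_iqr * iqr
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      flags[[r]] <- data.frame(subject = scans$subject[bad], roi = r,
                               age = scans$age[bad], value = x[bad],
                               stringsAsFactors = FALSE)
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(subject = character(), roi = character(),
               age = numeric(), value = numeric(), stringsAsFactors = FALSE)
  rownames(flags) <- NULL
  list(subjects = sort(unique(flags$subject)), flags = flags)
}

#' Fit the per-ROI random-slope mixed model
#'
#' Fits `gmv ~ covariates + age_c + (0 + age_c | subject)` by REML (ML via
#' `reml = FALSE`), where `age_c` is age centered at the cohort mean: with at
#' most three scans per subject only the random-slope model is estimable, so
#' no random intercept is included. The empirical-Bayes (BLUP) slope deviation
#' is extracted per subject; the subject-specific trajectory slope is the
#' fixed age effect plus this deviation.
#'
#' @param scans scan table (every subject must have >= 2 rows).
#' @param roi name of the ROI column to model.
#' @param covariates covariate column names.
#' @param reml use REML (default) or ML.
#' @return an object of class `roi_lmm_fit`: fixed effects `beta`, variance
#'   components `tau2` (random-slope) and `sigma2` (residual), per-subject
#'   `eb_slope` deviations, `subject_slope` (= beta age + deviation),
#'   `converged`, `logLik`, and the age centering constant.
#' @export
fit_roi_lmm <- function(scans, roi,
                        covariates = c("sex", "site", "handedness", "icv"),
                        reml = TRUE) {
  stopifnot(roi %in% names(scans))
  counts <- table(scans$subject)
  if (any(counts < 2))
    stop("every subject needs >= 2 observations; offender(s): ",
         paste(utils::head(names(counts)[counts < 2], 5), collapse = ", "),
         call. = FALSE)
  dat <- scans
  dat$.age_c <- dat$age - mean(dat$age)
  dat$.y <- dat[[roi]]
  Xcov <- covariate_matrix(dat[covariates], n = nrow(dat))
  check_full_rank(cbind(Xcov, age_c = dat$.age_c), what = "fixed-effect")

  fml <- stats::as.formula(paste(
    ".y ~", if (length(covariates)) paste(covariates, collapse = " + ") else "1",
    "+ .age_c + (0 + .age_c | subject)"))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(fml, data = dat, REML = reml,
                                control = lme4::lmerControl(calc.derivs = FALSE,
                                                            check.conv.singular = "ignore", check.scaleX = "ignore"))),
    error = function(e) e)
  subjects <- sort(unique(dat$subject))

  if (inherits(fit, "error")) {
    # fall back to tau2 = 0: plain OLS, zero EB deviations
    warning("mixed-model fit failed for ", roi, " (", conditionMessage(fit),
            "); falling back to OLS with tau2 = 0", call. = FALSE)
    ols <- stats::lm(fml_fixed <- stats::as.formula(paste(
      ".y ~", if (length(covariates)) paste(covariates, collapse = " + ") else "1",
      "+ .age_c")), data = dat)
    beta <- stats::coef(ols)
    eb <- stats::setNames(rep(0, length(subjects)), subjects)
    return(structure(list(beta = beta, tau2 = 0,
                          sigma2 = summary(ols)$sigma^2,
                          eb_slope = eb,
                          subject_slope = eb + unname(beta[".age_c"]),
                          converged = FALSE, logLik = as.numeric(stats::logLik(ols)),
                          age_center = mean(dat$age), roi = roi),
                     class = "roi_lmm_fit"))
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "subject"][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]
  re <- lme4::ranef(fit)$subject
  eb <- stats::setNames(re[[".age_c"]], rownames(re))[subjects]
  beta_age <- unname(lme4::fixef(fit)[".age_c"])
  conv <- length(fit@optinfo$conv$lme4) == 0
  structure(list(beta = lme4::fixef(fit), tau2 = tau2, sigma2 = sigma2,
                 eb_slope = eb, subject_slope = eb + beta_age,
                 converged = conv, logLik = as.numeric(stats::logLik(fit)),
                 age_center = mean(dat$age), roi = roi),
            class = "roi_lmm_fit")
}

#' @export
print.roi_lmm_fit <- function(x, ...) {
  cat("Random-slope LMM for", x$roi, "\n")
  cat(sprintf("  tau^2 = %.3f (mm^3/yr)^2, sigma^2 = %.3f mm^3^2\n", x$tau2, x$sigma2))
  cat(sprintf("  fixed age slope = %.3f mm^3/yr, %d subjects, converged: %s\n",
              unname(x$beta[".age_c"]), length(x$eb_slope), x$converged))
  invisible(x)
}

#' Assemble the subjects x ROIs trajectory matrix
#'
#' Runs [fit_roi_lmm()] per ROI and collects the subject-specific slopes
#' (fixed age effect + empirical-Bayes deviation) into a matrix with one row
#' per retained subject. Outliers are expected to have been excluded already.
#'
#' @param scans scan table.
#' @param rois ROI columns (default: all columns matching `^roi`).
#' @param covariates covariate column names.
#' @param reml passed to [fit_roi_lmm()].
#' @return a matrix with attributes `fits` (per-ROI `roi_lmm_fit` metadata)
#'   and class `trajectory_matrix`.
#' @export
build_trajectory_matrix <- function(scans,
                                    rois = grep("^roi", names(scans), value = TRUE),
                                    covariates = c("sex", "site", "handedness", "icv"),
                                    reml = TRUE) {
  subjects <- sort(unique(scans$subject))
  M <- matrix(NA_real_, length(subjects), length(rois),
              dimnames = list(subjects, rois))
  meta <- vector("list", length(rois))
  names(meta) <- rois
  for (r in rois) {
    fit <- tryCatch(fit_roi_lmm(scans, r, covariates, reml = reml),
                    error = function(e)
                      stop("trajectory fit failed fatally for ROI '", r, "': ",
                           conditionMessage(e), call. = FALSE))
    M[, r] <- fit$subject_slope[subjects]
    meta[[r]] <- list(beta_age = unname(fit$beta[".age_c"]), tau2 = fit$tau2,
                      sigma2 = fit$sigma2, converged = fit$converged)
  }
  if (any(!is.finite(M))) stop("non-finite trajectory entries", call. = FALSE)
  structure(M, fits = meta, class = c("trajectory_matrix", "matrix", "array"))
}
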