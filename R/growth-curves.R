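#' Fit the cross-sectional reference curve
#'
#' Least-squares fit of a GMV measure on a polynomial or natural-spline age
#' basis plus a study indicator (and optionally sex). The returned object
#' evaluates the curve (and its derivative) at any age within the observed
#' domain, at the average study offset.
#'
#' @param ref cross-sectional scan table with `age`, `study` and the value
#'   column.
#' @param value_col column to model (default `total_gmv`).
#' @param basis `"poly"` or `"ns"`.
#' @param degree polynomial degree (basis `"poly"`).
#' @param df spline basis dimension (basis `"ns"`).
#' @param use_sex include a sex main effect.
#' @return object of class `reference_curve` with `predict` / `deriv`
#'   closures, coefficients and the age domain.
#' @export
fit_reference_curve <- function(ref, value_col = "total_gmv",
                                basis = c("poly", "ns"), degree = 2, df = 5,
                                use_sex = FALSE) {
  basis <- match.arg(basis)
  domain <- range(ref$age)
  y <- ref[[value_col]]
  if (basis == "poly") {
    B <- outer(ref$age, seq_len(degree), `^`)
    colnames(B) <- paste0("age", seq_len(degree))
  } else {
    B <- splines::ns(ref$age, df = df)
    colnames(B) <- paste0("ns", seq_len(ncol(B)))
  }
  X <- cbind(`(Intercept)` = 1, B)
  studies <- sort(unique(ref$study))
  if (length(studies) > 1) {
    S <- sapply(studies[-1], function(s) as.numeric(ref$study == s))
    colnames(S) <- paste0("study", studies[-1])
    X <- cbind(X, S)
  }
  if (use_sex) X <- cbind(X, sexM = as.numeric(ref$sex == "M"))
  if (nrow(X) < ncol(X) + 2)
    stop("too few observations for the basis dimension", call. = FALSE)
  if (kappa(crossprod(X)) > 1e10)
    stop("ill-conditioned basis; use fewer degrees of freedom", call. = FALSE)
  fit <- ols_fit(y, X)
  if (is.null(fit)) stop("reference design is rank deficient", call. = FALSE)
  coefs <- stats::setNames(fit$coef, colnames(X))
  study_cols <- grep("^study", colnames(X), value = TRUE)
  study_prop <- if (length(study_cols))
    vapply(sub("^study", "", study_cols), function(s) mean(ref$study == s), 0) else numeric(0)
  sex_prop <- if (use_sex) mean(ref$sex == "M") else 0
  basis_fun <- if (basis == "poly") {
    function(a) { M <- outer(a, seq_len(degree), `^`); colnames(M) <- paste0("age", seq_len(degree)); M }
  } else {
    function(a) { M <- stats::predict(B, a); colnames(M) <- paste0("ns", seq_len(ncol(M))); M }
  }
  obj <- list(coefs = coefs, domain = domain, basis = basis, degree = degree,
              df = df, study_prop = study_prop, sex_prop = sex_prop,
              basis_fun = basis_fun, value_col = value_col)
  class(obj) <- "reference_curve"
  obj
}

#' Evaluate a reference curve
#' @param object a `reference_curve`.
#' @param ages ages (years); must lie inside the fitted domain.
#' @param ... unused.
#' @export
predict.reference_curve <- function(object, ages, ...) {
  if (any(ages < object$domain[1] - 1e-9 | ages > object$domain[2] + 1e-9))
    stop("age outside the reference domain [", object$domain[1], ", ",
         object$domain[2], "]", call. = FALSE)
  B <- object$basis_fun(ages)
  v <- object$coefs["(Intercept)"] + B %*% object$coefs[colnames(B)]
  if (length(object$study_prop))
    v <- v + sum(object$coefs[paste0("study", names(object$study_prop))] * object$study_prop)
  if ("sexM" %in% names(object$coefs))
    v <- v + object$coefs["sexM"] * object$sex_prop
  as.vector(v)
}

# Analytic (polynomial) or finite-difference (spline) derivative of the curve.
reference_deriv <- function(object, ages) {
  if (object$basis == "poly") {
    coefs <- object$coefs[paste0("age", seq_len(object$degree))]
    sapply(ages, function(a) sum(coefs * seq_len(object$degree) * a^(seq_len(object$degree) - 1)))
  } else {
    h <- 1e-4
    lo <- pmax(ages - h, object$domain[1]); hi <- pmin(ages + h, object$domain[2])
    (predict.reference_curve(object, hi) - predict.reference_curve(object, lo)) / (hi - lo)
  }
}

#' Group developmental curves as deviations from a reference
#'
#' The deviation `d_ij = y_ij - ref(age_ij)` is modelled by a quadratic linear
#' mixed model with random intercept and slope plus covariates. The
#' group-specific curve adds the group means of the empirical-Bayes random
#' effects to the population fixed part (evaluated at the covariate means) on
#' top of the reference; the 5th/95th percentile band is taken across
#' within-group individual fitted curves at each grid age.
#'
#' @param scans longitudinal scan table with the value column, `age`,
#'   `subject` and covariates.
#' @param labels named group vector.
#' @param reference a `reference_curve`.
#' @param value_col column holding the modelled GMV measure.
#' @param covariates covariate column names.
#' @param age_grid evaluation grid (years).
#' @return object of class `group_curve_set`: `curves` data.frame (group,
#'   age, fit, lo, hi, rate), model coefficients and metadata.
#' @export
fit_group_deviation_curves <- function(scans, labels, reference,
                                       value_col = "total_gmv",
                                       covariates = c("icv", "site"),
                                       age_grid = NULL) {
  stopifnot(!is.null(names(labels)))
  if (min(scans$age) < reference$domain[1] || max(scans$age) > reference$domain[2])
    stop("reference domain does not cover the observed ages", call. = FALSE)
  if (is.null(age_grid)) {
    # default grid: 0.25-yr steps over [5, 25] clipped to the reference domain
    lo <- ceiling(max(5, reference$domain[1]) * 4) / 4
    hi <- floor(min(25, reference$domain[2]) * 4) / 4
    age_grid <- seq(lo, hi, by = 0.25)
  }
  dat <- scans
  dat$.d <- dat[[value_col]] - predict(reference, dat$age)
  ctr <- mean(dat$age)
  dat$.t <- dat$age - ctr
  fml <- stats::as.formula(paste(
    ".d ~ .t + I(.t^2)",
    if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else "",
    "+ (1 + .t | subject)"))
  fit <- suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE,
                                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                                 check.conv.singular = "ignore", check.scaleX = "ignore")))
  fe <- lme4::fixef(fit)
  # fixed part at covariate means: average the non-age part of the design
  mm <- stats::model.matrix(fit)
  age_cols <- c(".t", "I(.t^2)")
  other <- setdiff(colnames(mm), age_cols)
  base_level <- sum(fe[other] * colMeans(mm[, other, drop = FALSE]))
  re <- lme4::ranef(fit)$subject
  subs <- rownames(re)
  g <- labels[subs]
  groups <- sort(unique(g))
  tgrid <- age_grid - ctr
  refv <- predict(reference, age_grid)
  refd <- reference_deriv(reference, age_grid)
  rows <- list()
  group_effects <- list()
  for (gr in groups) {
    in_g <- which(g == gr)
    b0 <- mean(re[in_g, "(Intercept)"]); b1 <- mean(re[in_g, ".t"])
    if (length(in_g) < 5)
      warning("group ", gr, " has < 5 subjects; band will be wide", call. = FALSE)
    fitv <- refv + base_level + fe[".t"] * tgrid + fe["I(.t^2)"] * tgrid^2 + b0 + b1 * tgrid
    ratev <- refd + fe[".t"] + 2 * fe["I(.t^2)"] * tgrid + b1
    # individual curves for the percentile band
    indiv <- outer(rep(1, length(in_g)), refv + base_level +
                     fe[".t"] * tgrid + fe["I(.t^2)"] * tgrid^2) +
      re[in_g, "(Intercept)"] + outer(re[in_g, ".t"], tgrid)
    qs <- apply(indiv, 2, stats::quantile, probs = c(0.05, 0.95), names = FALSE)
    rows[[as.character(gr)]] <- data.frame(group = gr, age = age_grid, fit = fitv,
                                           lo = qs[1, ], hi = qs[2, ], rate = ratev)
    group_effects[[as.character(gr)]] <- c(b0 = b0, b1 = b1)
  }
  curves <- do.call(rbind, rows)
  rownames(curves) <- NULL
  structure(list(curves = curves, fixed = fe, base_level = base_level,
                 age_center = ctr, reference = reference,
                 group_effects = group_effects, groups = groups,
                 domain = range(age_grid)),
            class = "group_curve_set")
}

#' Age-specific growth rates with sign classification
#'
#' Evaluates the analytic derivative of each group curve at the requested
#' ages and classifies the sign as increase / stable / decrease, with
#' `|rate| < rate_eps` counting as stable.
#'
#' @param curves a `group_curve_set`.
#' @param ages ages (years) inside the fitted domain.
#' @param rate_eps stability threshold (same units as the rate, mm^3/yr).
#' @return data.frame: group, age, rate, classification.
#' @export
growth_rate <- function(curves, ages, rate_eps = 500) {
  if (any(ages < curves$domain[1] - 1e-9 | ages > curves$domain[2] + 1e-9))
    stop("age outside the fitted domain", call. = FALSE)
  t <- ages - curves$age_center
  refd <- reference_deriv(curves$reference, ages)
  out <- list()
  for (gr in curves$groups) {
    b1 <- curves$group_effects[[as.character(gr)]]["b1"]
    r <- refd + curves$fixed[".t"] + 2 * curves$fixed["I(.t^2)"] * t + b1
    cls <- ifelse(abs(r) < rate_eps, "stable", ifelse(r > 0, "increase", "decrease"))
    out[[as.character(gr)]] <- data.frame(group = gr, age = ages,
                                          rate = unname(r), classification = cls)
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab
}

#' Two-stage peak total-GMV estimation
#'
#' Stage 1 fits the population ICV developmental curve on a natural-spline
#' age basis (default 5 df) with sex, age-by-sex and study terms and random
#' intercept + slope; stage 2 fits total GMV on a B-spline basis (default 12
#' df) with the stage-1 fitted ICV as covariate, sex, age-by-sex and study
#' terms, and random intercept + slope. Group curves add group-mean
#' empirical-Bayes effects; the peak is the argmax on a fine age grid, and a
#' per-subject peak (max of the subject-level fitted curve) is returned for
#' downstream mediation.
#'
#' @param scans longitudinal cohort scan table (`total_gmv`, `age`, `sex`,
#'   `icv`, `subject`); a `study` column is added as "cohort" when absent.
#' @param reference_scans cross-sectional reference scan table (same columns
#'   plus `study`).
#' @param labels named group vector for the cohort subjects.
#' @param icv_basis_df natural-spline df for the ICV stage.
#' @param gmv_basis_df B-spline df for the total-GMV stage.
#' @param grid_step age grid resolution in years.
#' @return object of class `peak_estimate`: `peaks` (group, peak_age,
#'   peak_gmv, boundary flag), `subject_peaks`, and the fitted age grid
#'   curves.
#' @export
estimate_peak <- function(scans, reference_scans, labels,
                          icv_basis_df = 5, gmv_basis_df = 12,
                          grid_step = 0.05) {
  stopifnot(!is.null(names(labels)))
  cols <- c("subject", "age", "sex", "icv", "total_gmv")
  sc <- scans[, cols]
  sc$study <- if ("study" %in% names(scans)) scans$study else "cohort"
  rf <- reference_scans[, c(cols, "study")]
  dat <- rbind(sc, rf)
  ctr <- mean(dat$age)
  dat$.t <- dat$age - ctr
  dat$.sexM <- as.numeric(dat$sex == "M")
  domain <- range(dat$age)

  # near-singular random-effect structures (e.g. a constant ICV) can abort
  # the optimizer; retry with a random intercept only before giving up
  fit_stage <- function(fixed, random_full, random_simple) {
    ctl <- lme4::lmerControl(calc.derivs = FALSE,
                             check.conv.singular = "ignore",
                             check.scaleX = "ignore",
                             check.nobs.vs.nRE = "ignore")
    for (rnd in c(random_full, random_simple)) {
      fml <- stats::as.formula(paste(fixed, "+", rnd))
      fit <- tryCatch(
        suppressMessages(lme4::lmer(fml, data = dat, REML = TRUE, control = ctl)),
        error = function(e) NULL)
      if (!is.null(fit)) return(fit)
    }
    warning("mixed-model stage failed; random effects dropped", call. = FALSE)
    NULL
  }

  # stage 1: population ICV curve
  icv_fixed <- "icv ~ splines::ns(.t, df = icv_basis_df) + .sexM + .t:.sexM + study"
  f1 <- fit_stage(icv_fixed, "(1 + .t | subject)", "(1 | subject)")
  if (is.null(f1))
    f1 <- stats::lm(stats::as.formula(icv_fixed), data = dat)
  grid <- seq(domain[1], domain[2], by = grid_step)
  nd <- data.frame(.t = grid - ctr, .sexM = mean(dat$.sexM),
                   study = sort(unique(dat$study))[1])
  icv_hat_grid <- stats::predict(f1, newdata = nd, re.form = NA)
  icv_at_raw <- stats::approxfun(grid, icv_hat_grid, rule = 2)
  # standardize the fitted-ICV covariate: on the raw mm^3 scale it is large
  # and nearly constant in age, which ill-conditions the stage-2 design
  icv_mu <- mean(icv_hat_grid); icv_sd <- stats::sd(icv_hat_grid)
  if (!is.finite(icv_sd) || icv_sd < 1e-8) icv_sd <- 1
  icv_at <- function(a) (icv_at_raw(a) - icv_mu) / icv_sd
  dat$.icv_hat <- icv_at(dat$age)

  # stage 2: total GMV on the B-spline basis with population ICV as covariate
  gmv_fixed <- "total_gmv ~ splines::bs(.t, df = gmv_basis_df) + .sexM + .t:.sexM + study + .icv_hat"
  f2 <- fit_stage(gmv_fixed, "(1 + .t | subject)", "(1 | subject)")
  if (is.null(f2)) stop("total-GMV stage could not be fitted", call. = FALSE)
  nd2 <- data.frame(.t = grid - ctr, .sexM = mean(dat$.sexM),
                    study = "cohort", .icv_hat = icv_at(grid))
  pop_curve <- stats::predict(f2, newdata = nd2, re.form = NA)
  re <- lme4::ranef(f2)$subject
  if (!".t" %in% colnames(re)) re$.t <- 0  # intercept-only fallback
  cohort_subs <- intersect(rownames(re), names(labels))
  g <- labels[cohort_subs]
  tgrid <- grid - ctr
  peaks <- list()
  curves <- list()
  for (gr in sort(unique(g))) {
    in_g <- cohort_subs[g == gr]
    b0 <- mean(re[in_g, "(Intercept)"]); b1 <- mean(re[in_g, ".t"])
    curve <- pop_curve + b0 + b1 * tgrid
    i <- which.max(curve)
    boundary <- i == 1L || i == length(curve)
    if (boundary)
      warning("group ", gr, ": peak at the age-domain boundary (no interior maximum)",
              call. = FALSE)
    peaks[[as.character(gr)]] <- data.frame(group = gr, peak_age = grid[i],
                                            peak_gmv = curve[i], boundary = boundary)
    curves[[as.character(gr)]] <- data.frame(group = gr, age = grid, fit = curve)
  }
  subj_peaks <- vapply(cohort_subs, function(s) {
    max(pop_curve + re[s, "(Intercept)"] + re[s, ".t"] * tgrid)
  }, 0)
  structure(list(peaks = do.call(rbind, peaks),
                 subject_peaks = data.frame(subject = cohort_subs,
                                            peak_gmv = unname(subj_peaks),
                                            stringsAsFactors = FALSE),
                 curves = do.call(rbind, curves),
                 icv_df = icv_basis_df, gmv_df = gmv_basis_df,
                 age_center = ctr, domain = domain),
            class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat("Two-stage peak total-GMV estimate\n")
  print(x$peaks, row.names = FALSE)
  invisible(x)
}
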