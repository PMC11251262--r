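#' ROI loadings for group classification from baseline GMV
#'
#' Multivariable logistic regression of the contrast label on all standardized
#' baseline ROI volumes plus covariates, fitted by iteratively reweighted
#' least squares with a small L2 ridge on the non-intercept coefficients so a
#' solution exists under (near-)separation. Loadings are the standardized ROI
#' coefficients; the top-k by absolute value form the selected subset.
#'
#' @param baseline_gmv data.frame with `subject` and ROI columns (one baseline
#'   row per subject).
#' @param labels named group vector.
#' @param contrast list with `case` and `control` group label sets
#'   (e.g. `list(case = 3, control = c(1, 2))`).
#' @param covariates data.frame keyed by `subject` (default none).
#' @param top_k size of the selected ROI subset.
#' @param ridge L2 penalty on standardized-scale coefficients.
#' @return object of class `loading_vector`: `loadings` (named, all ROIs),
#'   `se`, `selected` (top-k ROI names), `unstable` flag, contrast and
#'   covariate names.
#' @export
fit_loadings <- function(baseline_gmv, labels,
                         contrast = list(case = 3, control = c(1, 2)),
                         covariates = NULL, top_k = 10, ridge = 1e-4) {
  stopifnot(!is.null(names(labels)))
  rois <- grep("^roi", names(baseline_gmv), value = TRUE)
  g <- labels[baseline_gmv$subject]
  keep <- g %in% c(contrast$case, contrast$control)
  if (!any(g[keep] %in% contrast$case) || !any(g[keep] %in% contrast$control))
    stop("both contrast classes must be nonempty", call. = FALSE)
  y <- as.numeric(g[keep] %in% contrast$case)
  Z <- scale(as.matrix(baseline_gmv[keep, rois]))
  X <- Z
  if (!is.null(covariates)) {
    cv <- covariates[match(baseline_gmv$subject[keep], covariates$subject),
                     setdiff(names(covariates), "subject"), drop = FALSE]
    Xc <- covariate_matrix(cv, n = sum(keep))
    X <- cbind(Xc[, -1, drop = FALSE], Z)
  }
  fit <- ridge_logistic(y, X, ridge = ridge)
  if (fit$separation)
    warning("near-separation detected; ridge-regularized fit returned", call. = FALSE)
  loadings <- fit$coef[rois]
  se <- fit$se[rois]
  ord <- order(-abs(loadings))
  selected <- rois[ord][seq_len(min(top_k, length(rois)))]
  unstable <- max(abs(loadings) / se) < 3
  if (unstable)
    warning("no loading exceeds 3 SEs; top-k selection is unstable", call. = FALSE)
  structure(list(loadings = loadings, se = se, selected = selected,
                 unstable = unstable, contrast = contrast,
                 covariates = if (is.null(covariates)) character(0)
                              else setdiff(names(covariates), "subject"),
                 top_k = top_k, ridge = ridge),
            class = "loading_vector")
}

# IRLS logistic regression with an L2 ridge on non-intercept coefficients.
ridge_logistic <- function(y, X, ridge = 1e-4, max_iter = 100, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(ridge, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    A <- crossprod(X1, X1 * w) + pen
    b <- crossprod(X1, w * z)
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- as.vector(X1 %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  A <- crossprod(X1, X1 * w) + pen
  cov <- solve(A)
  separation <- max(abs(beta[-1])) > 10 || all(pmin(mu, 1 - mu) < 1e-6)
  list(coef = stats::setNames(as.vector(beta), colnames(X1)),
       se = stats::setNames(sqrt(diag(cov)), colnames(X1)),
       fitted = mu, separation = separation, iterations = it)
}

#' Reweighted GMV proxy score in a target cohort
#'
#' Standardizes the selected ROI columns within the target cohort, forms the
#' weighted sum with the discovery loadings, and standardizes the result.
#' Adding a constant to a target ROI column therefore leaves the score
#' unchanged.
#'
#' @param target_gmv data.frame with `subject` and the selected ROI columns.
#' @param loadings a `loading_vector`.
#' @return data.frame `subject`, `score` (mean 0, sd 1), with the contrast as
#'   an attribute.
#' @export
reweight_gmv <- function(target_gmv, loadings) {
  sel <- loadings$selected
  missing <- setdiff(sel, names(target_gmv))
  if (length(missing))
    stop("target cohort lacks ROI column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  w <- loadings$loadings[sel]
  if (all(w == 0)) stop("all selected weights are zero (degenerate score)", call. = FALSE)
  Z <- scale(as.matrix(target_gmv[, sel]))
  raw <- as.vector(Z %*% w)
  score <- (raw - mean(raw)) / stats::sd(raw)
  out <- data.frame(subject = target_gmv$subject, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- loadings$contrast
  out
}

#' Correlate a proxy score with outcomes
#'
#' Pearson correlation between the covariate-residualized score and each
#' covariate-residualized outcome, with a t-test per correlation and BH-FDR
#' across outcomes.
#'
#' @param score data.frame `subject`, `score`.
#' @param outcomes data.frame `subject` plus outcome columns.
#' @param covariates optional data.frame keyed by `subject`.
#' @return data.frame: outcome, r, t, p, p_adj, n.
#' @export
validate_proxy <- function(score, outcomes, covariates = NULL) {
  shared <- intersect(score$subject, outcomes$subject)
  if (length(shared) < 10) stop("fewer than 10 shared subjects", call. = FALSE)
  s <- score$score[match(shared, score$subject)]
  cv <- if (!is.null(covariates))
    covariates[match(shared, covariates$subject),
               setdiff(names(covariates), "subject"), drop = FALSE]
  rs <- residualize(s, cv)
  ocols <- setdiff(names(outcomes), "subject")
  rows <- lapply(ocols, function(oc) {
    yv <- outcomes[[oc]][match(shared, outcomes$subject)]
    ok <- !is.na(yv)
    ry <- residualize(yv[ok], if (is.null(cv)) NULL else cv[ok, , drop = FALSE])
    r <- stats::cor(rs[ok], ry)
    n <- sum(ok)
    tval <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(outcome = oc, r = r, t = tval,
               p = 2 * stats::pt(-abs(tval), n - 2), n = n,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- bh_fdr(tab$p)
  rownames(tab) <- NULL
  tab
}
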