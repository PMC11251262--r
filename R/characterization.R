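#' Residualize values on a covariate design
#'
#' Ordinary-least-squares residuals of `values` on the covariates (an
#' intercept is always included, so residuals are mean-centered).
#'
#' @param values numeric vector.
#' @param covariates data.frame / matrix of covariates, or NULL for
#'   intercept-only (plain mean-centering).
#' @return residual vector.
#' @export
residualize <- function(values, covariates = NULL) {
  X <- covariate_matrix(covariates, n = length(values))
  check_full_rank(X)
  qr.resid(qr(X), values)
}

#' Pairwise group contrasts of ROI trajectories
#'
#' Two-sample two-tailed pooled-variance t-tests on covariate-residualized
#' slopes per ROI (Welch available by flag), Cohen's d with the pooled sd,
#' Benjamini-Hochberg FDR across ROIs, and the top-k ROIs by absolute t.
#' Signs are `pair[1]` minus `pair[2]`.
#'
#' @param traj subjects x ROIs trajectory matrix.
#' @param labels group label per subject (aligned with rows of `traj`).
#' @param pair length-2 vector of group labels to contrast.
#' @param covariates optional covariate data.frame (rows aligned with `traj`).
#' @param top_k how many top discriminating ROIs to report.
#' @param welch use Welch's t instead of pooled.
#' @return list: `table` (roi, t, d, p, p_adj, n1, n2) sorted by |t|, and
#'   `top` (character vector of top-k ROIs).
#' @export
roi_contrasts <- function(traj, labels, pair, covariates = NULL, top_k = 5,
                          welch = FALSE) {
  X <- as.matrix(traj)
  stopifnot(length(labels) == nrow(X), length(pair) == 2)
  in_pair <- labels %in% pair
  if (!all(table(factor(labels[in_pair], levels = pair)) >= 2))
    stop("both groups need >= 2 subjects", call. = FALSE)
  Xs <- X[in_pair, , drop = FALSE]
  g <- labels[in_pair]
  cov_s <- if (!is.null(covariates)) as.data.frame(covariates)[in_pair, , drop = FALSE]
  res <- lapply(colnames(Xs), function(r) {
    v <- residualize(Xs[, r], cov_s)
    x1 <- v[g == pair[1]]; x2 <- v[g == pair[2]]
    n1 <- length(x1); n2 <- length(x2)
    sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
    diff <- mean(x1) - mean(x2)
    if (sp2 <= .Machine$double.eps^1.5 * (1 + diff^2)) {
      warning("zero pooled variance for ", r, "; reporting d = Inf sentinel",
              call. = FALSE)
      tval <- sign(diff) * Inf; d <- sign(diff) * Inf; p <- 0
    } else if (welch) {
      tt <- stats::t.test(x1, x2)
      tval <- unname(tt$statistic); p <- tt$p.value; d <- diff / sqrt(sp2)
    } else {
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      tval <- diff / se
      p <- 2 * stats::pt(-abs(tval), n1 + n2 - 2)
      d <- diff / sqrt(sp2)
    }
    data.frame(roi = r, t = tval, d = d, p = p, n1 = n1, n2 = n2,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$p_adj <- bh_fdr(tab$p)
  tab <- tab[order(-abs(tab$t)), c("roi", "t", "d", "p", "p_adj", "n1", "n2")]
  rownames(tab) <- NULL
  list(table = tab, top = utils::head(tab$roi, top_k), pair = pair)
}

#' Group contrasts of longitudinal outcomes
#'
#' Linear model of each outcome on a group indicator plus covariates, with
#' optional adjustment for the subject's baseline value of the same outcome.
#' The group-coefficient t-test is reported together with a
#' covariate-residualized Cohen's d; FDR is applied within the declared
#' outcome families.
#'
#' @param outcomes data.frame with columns `subject`, `visit` and outcome
#'   columns; the contrast is evaluated at `visit = at_visit`.
#' @param labels named group vector (names = subject ids).
#' @param pair groups to contrast (`pair[1]` vs `pair[2]`).
#' @param covariates data.frame keyed by `subject` with covariate columns.
#' @param baseline_adjust include the baseline value of the outcome.
#' @param at_visit,baseline_visit visit labels.
#' @param families named vector mapping outcome -> FDR family (single family
#'   when NULL).
#' @return data.frame: outcome, estimate, t, d, p, p_adj, n, family.
#' @export
outcome_contrasts <- function(outcomes, labels, pair, covariates = NULL,
                              baseline_adjust = FALSE, at_visit = "followup",
                              baseline_visit = "baseline", families = NULL) {
  stopifnot(!is.null(names(labels)))
  ocols <- setdiff(names(outcomes), c("subject", "visit"))
  cur <- outcomes[outcomes$visit == at_visit, , drop = FALSE]
  base <- outcomes[outcomes$visit == baseline_visit, , drop = FALSE]
  rows <- lapply(ocols, function(oc) {
    y <- cur[[oc]]
    sub <- cur$subject
    g <- labels[sub]
    keep <- g %in% pair & !is.na(y)
    if (!any(keep & g == pair[1]) || !any(keep & g == pair[2])) {
      warning("outcome ", oc, " missing for an entire group; skipped", call. = FALSE)
      return(NULL)
    }
    df <- data.frame(y = y[keep], grp = as.numeric(g[keep] == pair[1]))
    if (!is.null(covariates)) {
      cv <- covariates[match(sub[keep], covariates$subject),
                       setdiff(names(covariates), "subject"), drop = FALSE]
      df <- cbind(df, cv)
    }
    if (baseline_adjust) {
      df$.baseline <- base[[oc]][match(sub[keep], base$subject)]
      df <- df[!is.na(df$.baseline), , drop = FALSE]
    }
    fit <- stats::lm(y ~ ., data = df)
    sm <- summary(fit)$coefficients
    resid_y <- residualize(df$y, df[, setdiff(names(df), c("y", "grp")), drop = FALSE])
    d <- cohens_d(resid_y[df$grp == 1], resid_y[df$grp == 0])
    data.frame(outcome = oc, estimate = sm["grp", 1], t = sm["grp", 3], d = d,
               p = sm["grp", 4], n = nrow(df),
               family = if (is.null(families)) "all" else families[[oc]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(tab)
  tab$p_adj <- bh_fdr(tab$p, tab$family)
  rownames(tab) <- NULL
  tab[, c("outcome", "estimate", "t", "d", "p", "p_adj", "n", "family")]
}

cohens_d <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  if (is.na(sp2) || sp2 == 0) return(sign(mean(x1) - mean(x2)) * Inf)
  (mean(x1) - mean(x2)) / sqrt(sp2)
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up FDR adjustment applied separately within each declared family
#' ("correction within scales").
#'
#' @param p p-values in \[0, 1\].
#' @param families optional family label per p-value.
#' @return adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p, families = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]", call. = FALSE)
  if (is.null(families)) return(stats::p.adjust(p, method = "BH"))
  stopifnot(length(families) == length(p))
  out <- p
  for (f in unique(families)) {
    i <- which(families == f)
    out[i] <- stats::p.adjust(p[i], method = "BH")
  }
  out
}
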