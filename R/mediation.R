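#' Single-mediator mediation with nonparametric bootstrap
#'
#' Ordinary least squares for the mediator model `M ~ X + covariates` (path a)
#' and the outcome model `Y ~ X + M + covariates` (paths c' and b); the
#' indirect effect is `a * b`, the total effect `c' + a * b` (identical to the
#' X coefficient of the reduced model `Y ~ X + covariates`, an OLS identity),
#' and the mediation proportion `a * b / (c' + a * b)`. Case-resampling
#' bootstrap (paired rows) provides standard errors, percentile 95\% CIs and
#' a two-sided normal-approximation p per quantity. The proportion is
#' reported as NA when `|total| < 1e-8`.
#'
#' @param X exposure vector.
#' @param M mediator vector.
#' @param Y outcome vector.
#' @param covariates optional data.frame of covariates.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return object of class `mediation_result` with `estimates` (a, b, cprime,
#'   indirect, total, proportion), `se`, `ci` (2.5/97.5 percentile), `p`,
#'   `B`, `seed`, `n`.
#' @export
fit_mediation <- function(X, M, Y, covariates = NULL, B = 1000, seed = 1L) {
  df <- data.frame(X = X, M = M, Y = Y)
  Xc <- covariate_matrix(covariates, n = nrow(df))
  cc <- stats::complete.cases(df) & stats::complete.cases(Xc)
  df <- df[cc, , drop = FALSE]
  Xc <- Xc[cc, , drop = FALSE]
  if (nrow(df) < 30) stop("fewer than 30 complete cases", call. = FALSE)
  if (stats::var(df$X) == 0 || stats::var(df$M) == 0)
    stop("zero variance in X or M", call. = FALSE)
  check_full_rank(Xc)

  point <- mediation_paths(df$X, df$M, df$Y, Xc)
  boots <- matrix(NA_real_, B, 6,
                  dimnames = list(NULL, c("a", "b", "cprime", "indirect",
                                          "total", "proportion")))
  n <- nrow(df)
  with_seed(seed, {
    for (i in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      boots[i, ] <- mediation_paths(df$X[idx], df$M[idx], df$Y[idx],
                                    Xc[idx, , drop = FALSE])
    }
  })
  se <- apply(boots, 2, stats::sd, na.rm = TRUE)
  ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  p <- 2 * stats::pnorm(-abs(point / se))
  structure(list(estimates = point, se = se,
                 ci = stats::setNames(as.data.frame(t(ci)), c("lower", "upper")),
                 p = p, B = B, seed = seed, n = n),
            class = "mediation_result")
}

# One evaluation of the two OLS path models; returns the six quantities.
mediation_paths <- function(x, m, y, Xc) {
  Xm <- cbind(Xc, X = x)
  Xy <- cbind(Xc, X = x, M = m)
  cm <- qr.coef(qr(Xm), m)
  cy <- qr.coef(qr(Xy), y)
  a <- unname(cm["X"]); b <- unname(cy["M"]); cp <- unname(cy["X"])
  indirect <- a * b
  total <- cp + indirect
  prop <- if (abs(total) < 1e-8) NA_real_ else indirect / total
  c(a = a, b = b, cprime = cp, indirect = indirect, total = total,
    proportion = prop)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation (n = %d, B = %d bootstrap resamples)\n", x$n, x$B))
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    lower = x$ci$lower, upper = x$ci$upper, p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Equivalence ("inferiority") test of a correlation against a margin
#'
#' Two one-sided tests on the Fisher-z scale of the partial (covariate-
#' residualized) Pearson correlation, with standard error `1/sqrt(n-3)`:
#' `H0: |rho| >= delta` is rejected when both one-sided p-values fall below
#' alpha, concluding `|rho| < delta`.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame residualized out of both.
#' @param delta equivalence margin in correlation units, in (0, 1).
#' @param alpha test level for the conclusion flag.
#' @return object of class `inferiority_result`: `r`, `n`, `delta`,
#'   `p_upper`, `p_lower`, `p_inferiority` (their max), `conclusion`.
#' @export
inferiority_test <- function(x, y, covariates = NULL, delta = 0.05,
                             alpha = 0.05) {
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  cv <- if (!is.null(covariates)) as.data.frame(covariates)[ok, , drop = FALSE]
  rx <- residualize(x, cv)
  ry <- residualize(y, cv)
  n <- length(rx)
  if (n < 10) stop("fewer than 10 complete cases after residualization",
                   call. = FALSE)
  r <- stats::cor(rx, ry)
  zr <- atanh(r); zd <- atanh(delta)
  s <- sqrt(n - 3)
  p_upper <- 1 - stats::pnorm((zd - zr) * s)   # H0: rho >= delta
  p_lower <- 1 - stats::pnorm((zr + zd) * s)   # H0: rho <= -delta
  p_inf <- max(p_upper, p_lower)
  structure(list(r = r, n = n, delta = delta, p_upper = p_upper,
                 p_lower = p_lower, p_inferiority = p_inf,
                 conclusion = p_inf < alpha, alpha = alpha),
            class = "inferiority_result")
}

#' @export
print.inferiority_result <- function(x, ...) {
  cat(sprintf("Correlation equivalence test: r = %.4f (n = %d), margin = %.3f\n",
              x$r, x$n, x$delta))
  cat(sprintf("  p_inferiority = %.3g -> %s |rho| < %.3f at alpha = %.2f\n",
              x$p_inferiority,
              if (x$conclusion) "conclude" else "cannot conclude",
              x$delta, x$alpha))
  invisible(x)
}
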