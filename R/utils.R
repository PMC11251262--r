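#' @keywords internal
"_PACKAGE"

# Deterministic substream seed derived from a master seed and a stream name.
# Simple polynomial rolling hash over the name, folded into the master seed;
# stays inside the 32-bit signed range R accepts in set.seed().
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647
  h <- as.double(seed) %% m
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% m
  as.integer(max(1, h))
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# OLS of y on X (X includes the intercept column); returns coefficients,
# standard errors, t and two-sided p for every column. Used by the per-marker
# scans where a full lm() per marker would dominate runtime.
ols_fit <- function(y, X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) return(NULL)
  coefs <- qr.coef(qrx, y)
  res <- y - X %*% coefs
  df <- length(y) - ncol(X)
  if (df <= 0) return(NULL)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- coefs / se
  list(coef = as.vector(coefs), se = as.vector(se), t = as.vector(tval),
       p = 2 * stats::pt(-abs(as.vector(tval)), df), df = df,
       residuals = as.vector(res), sigma2 = sigma2)
}

# Model matrix with intercept from a data.frame of covariates (possibly NULL).
# Categorical columns become treatment-coded indicators with the
# lexicographically first level as reference, for determinism.
covariate_matrix <- function(covariates, n = NULL) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    stopifnot(!is.null(n))
    return(matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]], levels = sort(unique(covariates[[j]])))
    else if (is.factor(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]], levels = sort(levels(covariates[[j]])))
  }
  stats::model.matrix(~ ., data = covariates)
}

# Error if the design matrix is rank deficient, naming the offending columns.
check_full_rank <- function(X, what = "covariate") {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop(sprintf("%s design is rank deficient; collinear columns: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
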