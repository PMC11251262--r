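# Shared fixtures, built in code and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small, fast cohort for structural tests.
tiny_config <- function(n_subjects = 120, n_snps = 40, n_cpgs = 40,
                        n_ref_subjects = 150, n_adult = 200, seed = 101L, ...) {
  sim_config(n_subjects = n_subjects, n_snps = n_snps, n_cpgs = n_cpgs,
             n_ref_subjects = n_ref_subjects, n_adult = n_adult, seed = seed,
             ...)
}

# The default study-condition cohort (n = 1500), with its trajectory matrix,
# PCA and selected clustering. Built once; several test files and the
# acceptance suite reuse it.
default_discovery <- function() {
  cached("default_discovery", function() {
    cfg <- sim_config(seed = 1L)
    bundle <- simulate_cohort(cfg)
    traj <- build_trajectory_matrix(bundle$scans)
    proj <- standardize_project(traj)
    sel <- select_k(proj$scores, seed = substream_seed(1L, "select_k"))
    list(config = cfg, bundle = bundle, traj = traj, proj = proj, sel = sel)
  })
}

# Deterministic longitudinal toy: n subjects, visits at given ages, one ROI
# generated as intercept + subject slope * (age - mean) + noise.
make_toy_scans <- function(n = 20, ages = c(14, 19, 23), slope_sd = 5,
                           resid_sd = 3, intercept = 100, seed = 42) {
  set.seed(seed)
  slopes <- rnorm(n, 0, slope_sd)
  rows <- expand.grid(subject = sprintf("T%02d", seq_len(n)), age = ages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[order(rows$subject, rows$age), ]
  tc <- rows$age - mean(ages)
  rows$roi01 <- intercept + slopes[match(rows$subject, sprintf("T%02d", seq_len(n)))] * tc +
    rnorm(nrow(rows), 0, resid_sd)
  rownames(rows) <- NULL
  attr(rows, "true_slopes") <- setNames(slopes, sprintf("T%02d", seq_len(n)))
  rows
}

# GLS / BLUP oracle by explicit matrix inversion for the random-slope-only
# model y_i = X_i beta + b_i t_i + eps, b_i ~ N(0, tau2), eps ~ N(0, sigma2).
gls_blup_oracle <- function(y, X, t, subject, tau2, sigma2) {
  subs <- sort(unique(subject))
  XtVX <- matrix(0, ncol(X), ncol(X))
  XtVy <- numeric(ncol(X))
  Vinv <- list()
  for (s in subs) {
    i <- which(subject == s)
    V <- sigma2 * diag(length(i)) + tau2 * tcrossprod(t[i])
    Vi <- solve(V)
    Vinv[[s]] <- Vi
    XtVX <- XtVX + t(X[i, , drop = FALSE]) %*% Vi %*% X[i, , drop = FALSE]
    XtVy <- XtVy + t(X[i, , drop = FALSE]) %*% Vi %*% y[i]
  }
  beta <- solve(XtVX, XtVy)
  b <- vapply(subs, function(s) {
    i <- which(subject == s)
    r <- y[i] - X[i, , drop = FALSE] %*% beta
    tau2 * as.numeric(t(t[i]) %*% Vinv[[s]] %*% r)
  }, 0)
  list(beta = as.vector(beta), blup = setNames(b, subs))
}

# Hand-rolled greedy clumping oracle used against clump_locus.
greedy_clump_oracle <- function(summary, dosages, window, r2_max) {
  s <- summary[order(summary$p), ]
  claimed <- character(0)
  index <- character(0)
  for (i in seq_len(nrow(s))) {
    id <- s$id[i]
    if (id %in% claimed) next
    index <- c(index, id)
    claimed <- c(claimed, id)
    for (j in seq_len(nrow(s))) {
      cand <- s$id[j]
      if (cand %in% claimed) next
      if (s$chr[j] == s$chr[i] && abs(s$pos[j] - s$pos[i]) <= window &&
          (stats::cor(dosages[, id], dosages[, cand]))^2 > r2_max)
        claimed <- c(claimed, cand)
    }
  }
  index
}
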