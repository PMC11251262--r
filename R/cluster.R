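#' Standardize the trajectory matrix and project on principal components
#'
#' Columns are z-scored (denominator n-1), the SVD of the standardized matrix
#' taken, and the smallest number of components whose cumulative explained
#' variance reaches `variance_target` retained. Component signs follow the
#' convention that each rotation column's largest-magnitude loading is
#' positive, so rotations are reproducible.
#'
#' @param traj subjects x ROIs matrix.
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @param scale. z-score the columns before the SVD (default TRUE; FALSE
#'   keeps the raw column variances, centering only).
#' @return list with `model` (class `pc_model`: center, scale, rotation,
#'   ratios, `m_selected`) and `scores` (n x m_selected matrix).
#' @export
standardize_project <- function(traj, variance_target = 0.80, scale. = TRUE) {
  if (variance_target <= 0 || variance_target > 1)
    stop("variance_target must lie in (0, 1]", call. = FALSE)
  X <- as.matrix(traj)
  if (nrow(X) < 2) stop("need >= 2 subjects", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!scale.) sds <- rep(1, ncol(X))
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  sv <- svd(Z)
  # sign convention: largest-|loading| entry positive in each rotation column
  for (j in seq_len(ncol(sv$v))) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  ev <- sv$d^2
  ratios <- ev / sum(ev)
  m <- which(cumsum(ratios) >= variance_target - 1e-12)[1]
  rotation <- sv$v
  dimnames(rotation) <- list(colnames(X), paste0("PC", seq_len(ncol(rotation))))
  scores <- Z %*% rotation[, seq_len(m), drop = FALSE]
  rownames(scores) <- rownames(X)
  model <- structure(list(center = ctr, scale = sds, rotation = rotation,
                          ratios = ratios, m_selected = m,
                          variance_target = variance_target),
                     class = "pc_model")
  list(model = model, scores = scores)
}

# k-means++ initial centers (Arthur & Vassilvitskii seeding).
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  if (k > 1) for (j in 2:k) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Fit k-means with k-means++ restarts
#'
#' Lloyd's algorithm (via `stats::kmeans`) started from k-means++ seeds; the
#' best of `restarts` runs by within-cluster sum of squares is kept. Empty
#' clusters at convergence trigger a re-seed of that restart.
#'
#' @param scores numeric matrix of points.
#' @param k number of clusters (<= number of points).
#' @param restarts number of independent k-means++ starts.
#' @param max_iter Lloyd iteration cap per start.
#' @param seed integer seed for the seeding randomness.
#' @return an object of class `cluster_solution` with labels, centroids,
#'   `wss`, `bss`, `tss`, `ratio` (= bss/tss), sizes, restarts and seed.
#' @export
kmeans_fit <- function(scores, k, restarts = 50, max_iter = 300, seed = 1L) {
  X <- as.matrix(scores)
  if (k > nrow(X)) stop("k exceeds the number of points", call. = FALSE)
  if (any(!is.finite(X))) stop("scores must be finite", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      km <- NULL
      for (attempt in 1:5) {
        init <- kmeanspp_init(X, k)
        km <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = init, iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
    structure(list(k = k, labels = unname(best$cluster),
                   centroids = best$centers,
                   wss = best$tot.withinss, bss = best$betweenss,
                   tss = best$totss, ratio = best$betweenss / best$totss,
                   sizes = unname(best$size), restarts = restarts, seed = seed),
              class = "cluster_solution")
  })
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, sizes = %s\n", x$k,
              paste(x$sizes, collapse = "/")))
  cat(sprintf("  BSS/TSS = %.4f (WSS = %.4g, TSS = %.4g)\n", x$ratio, x$wss, x$tss))
  invisible(x)
}

#' Select the number of clusters by constrained elbow curvature
#'
#' For every candidate k the best k-means solution is computed; k is
#' admissible when its smallest cluster holds at least `min_frac` of the
#' points. Among admissible k, the one maximizing the discrete curvature of
#' the within-sum-of-squares curve on the log scale,
#' `log WSS(k-1) - 2 log WSS(k) + log WSS(k+1)`, is selected (ties: smallest
#' k). The log scale makes the elbow criterion invariant to the overall
#' variance scale, so a small, very distant cluster and a finer split of the
#' bulk are judged by their relative (not absolute) variance reductions. The
#' curve is extended one k below and above the range so every candidate has a
#' curvature (`WSS(1) = TSS`).
#'
#' @param scores points in retained-PC space.
#' @param k_range candidate cluster counts.
#' @param min_frac minimum admissible cluster fraction.
#' @param restarts,max_iter,seed passed to [kmeans_fit()].
#' @return list: `k` (selected), `solution` (its `cluster_solution`),
#'   `diagnostics` (k, wss, min_size, admissible, curvature) and
#'   `low_curvature` flag (near-flat elbow curve).
#' @export
select_k <- function(scores, k_range = 2:8, min_frac = 0.04, restarts = 50,
                     max_iter = 300, seed = 1L) {
  if (!length(k_range)) stop("k_range is empty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(scores)
  ks <- (min(k_range) - 1L):(max(k_range) + 1L)
  ks <- ks[ks >= 1 & ks <= n]
  sols <- list()
  wss <- stats::setNames(rep(NA_real_, length(ks)), ks)
  for (k in ks) {
    sol <- kmeans_fit(scores, k, restarts = restarts, max_iter = max_iter,
                      seed = substream_seed(seed, paste0("k", k)))
    sols[[as.character(k)]] <- sol
    wss[as.character(k)] <- sol$wss
  }
  diag <- data.frame(k = k_range,
                     wss = wss[as.character(k_range)],
                     min_size = vapply(as.character(k_range),
                                       function(k) min(sols[[k]]$sizes), 0))
  diag$admissible <- diag$min_size >= min_frac * n
  lwss <- log(pmax(wss, 1e-12 * sols[[as.character(ks[1])]]$tss))
  diag$curvature <- vapply(k_range, function(k) {
    lo <- as.character(k - 1L); hi <- as.character(k + 1L)
    if (!lo %in% names(wss) || !hi %in% names(wss)) return(NA_real_)
    lwss[lo] - 2 * lwss[as.character(k)] + lwss[hi]
  }, 0)
  # structureless reference: WSS of unclustered data decays like a smooth
  # power law in k, which has its own log-curvature; structure shows up as
  # curvature in excess of that fitted decay
  ok <- wss > 0
  alpha <- stats::coef(stats::lm(log(wss[ok]) ~ log(ks[ok])))[2]
  null_curv <- vapply(k_range, function(k) {
    if (k <= 1) return(NA_real_)
    abs(alpha) * log(k^2 / ((k - 1) * (k + 1)))
  }, 0)
  diag$excess <- diag$curvature - null_curv
  cand <- diag[diag$admissible & !is.na(diag$curvature), ]
  if (!nrow(cand))
    stop("no admissible k in range; consider lowering min_frac", call. = FALSE)
  k_sel <- cand$k[which.max(cand$curvature)]  # which.max: first max = smallest k
  low_curv <- max(cand$excess, na.rm = TRUE) < 0.1
  if (low_curv)
    warning("elbow curve is nearly flat; cluster structure is weak", call. = FALSE)
  list(k = k_sel, solution = sols[[as.character(k_sel)]],
       diagnostics = diag, low_curvature = low_curv)
}

#' Permutation test of clustering validity
#'
#' Each permutation independently shuffles the subject order within every ROI
#' column of the trajectory matrix — destroying cross-ROI correlation while
#' preserving the marginals — then reruns the dimension reduction and k-means
#' at the observed k. The p-value uses the add-one correction
#' `p = (1 + #\{null ratio >= observed\}) / (B + 1)`.
#'
#' @param traj trajectory matrix.
#' @param k_obs cluster count of the observed solution.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param restarts_perm k-means restarts inside the permutation loop.
#' @param variance_target passed to [standardize_project()].
#' @param observed_ratio observed BSS/TSS; computed here (with
#'   `restarts_perm` restarts) when NULL.
#' @return an object of class `permutation_result`: `observed`, `null_ratios`,
#'   `p`, `B`, `seed`.
#' @export
permutation_validity <- function(traj, k_obs, B = 1000, seed = 1L,
                                 restarts_perm = 10, variance_target = 0.80,
                                 observed_ratio = NULL) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  X <- as.matrix(traj)
  if (all(apply(X, 2, stats::sd) == 0)) stop("constant matrix", call. = FALSE)
  if (is.null(observed_ratio)) {
    obs <- standardize_project(X, variance_target)
    observed_ratio <- kmeans_fit(obs$scores, k_obs, restarts = restarts_perm,
                                 seed = substream_seed(seed, "observed"))$ratio
  }
  n <- nrow(X)
  null_ratios <- numeric(B)
  for (b in seq_len(B)) {
    perm <- with_seed(substream_seed(seed, paste0("perm", b)), {
      Xp <- X
      for (j in seq_len(ncol(X))) Xp[, j] <- X[sample.int(n), j]
      Xp
    })
    pr <- suppressWarnings(standardize_project(perm, variance_target))
    null_ratios[b] <- kmeans_fit(pr$scores, k_obs, restarts = restarts_perm,
                                 seed = substream_seed(seed, paste0("km", b)))$ratio
  }
  p <- (1 + sum(null_ratios >= observed_ratio)) / (B + 1)
  structure(list(observed = observed_ratio, null_ratios = null_ratios,
                 p = p, B = B, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Cluster-validity permutation test: observed BSS/TSS = %.4f\n",
              x$observed))
  cat(sprintf("  B = %d, p = %.4g (add-one correction)\n", x$B, x$p))
  invisible(x)
}
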