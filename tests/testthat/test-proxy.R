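make_baseline <- function(n = 400, n_rois = 8, shift_roi = NULL, shift = 0,
                          frac_case = 0.2, seed = 3) {
  set.seed(seed)
  g <- stats::setNames(ifelse(runif(n) < frac_case, 3, sample(1:2, n, TRUE)),
                       sprintf("P%04d", 1:n))
  G <- matrix(rnorm(n * n_rois, 5000, 300), n, n_rois,
              dimnames = list(NULL, sprintf("roi%02d", 1:n_rois)))
  if (!is.null(shift_roi)) G[g == 3, shift_roi] <- G[g == 3, shift_roi] + shift
  list(gmv = data.frame(subject = names(g), G, check.names = FALSE),
       labels = g)
}

test_that("a strongly shifted ROI ranks first among the loadings", {
  mb <- make_baseline(shift_roi = "roi05", shift = -400)
  lv <- fit_loadings(mb$gmv, mb$labels, top_k = 3)
  expect_equal(lv$selected[1], "roi05")
  expect_lt(lv$loadings["roi05"], 0)
  expect_false(lv$unstable)
})

test_that("null labels produce small loadings and an instability warning", {
  mb <- make_baseline(n = 2000, seed = 8)
  expect_warning(lv <- fit_loadings(mb$gmv, mb$labels), "unstable")
  expect_true(all(abs(lv$loadings) < 3 * lv$se))
  expect_true(lv$unstable)
})

test_that("duplicating every subject leaves loadings essentially unchanged", {
  mb <- make_baseline(n = 300, shift_roi = "roi02", shift = -300, seed = 9)
  lv1 <- fit_loadings(mb$gmv, mb$labels)
  gmv2 <- rbind(mb$gmv, mb$gmv)
  lv2 <- fit_loadings(gmv2, mb$labels)
  expect_equal(lv1$loadings, lv2$loadings, tolerance = 1e-2)
})

test_that("reweighting is the advertised standardized weighted sum", {
  # 3 selected ROIs with weights (0.1, -0.2, 0.3); verify against the
  # hand-computed weighted sum of within-target z-scores
  lv <- structure(list(loadings = c(roi01 = 0.1, roi02 = -0.2, roi03 = 0.3),
                       selected = c("roi01", "roi02", "roi03"),
                       contrast = list(case = 3, control = 1:2)),
                  class = "loading_vector")
  set.seed(10)
  tg <- data.frame(subject = sprintf("T%02d", 1:50),
                   roi01 = rnorm(50), roi02 = rnorm(50), roi03 = rnorm(50))
  px <- reweight_gmv(tg, lv)
  raw <- as.vector(scale(as.matrix(tg[, 2:4])) %*% c(0.1, -0.2, 0.3))
  expect_equal(px$score, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  expect_equal(mean(px$score), 0, tolerance = 1e-12)
  expect_equal(sd(px$score), 1, tolerance = 1e-12)

  # adding a constant to a target ROI column does not move the score
  tg2 <- tg; tg2$roi02 <- tg2$roi02 + 100
  expect_equal(reweight_gmv(tg2, lv)$score, px$score, tolerance = 1e-12)

  lv0 <- lv; lv0$loadings[] <- 0
  expect_error(reweight_gmv(tg, lv0), "degenerate")
  expect_error(reweight_gmv(tg[, 1:3], lv), "roi03")
})

test_that("in-sample proxy score separates the contrast classes", {
  mb <- make_baseline(n = 600, shift_roi = c("roi01", "roi04"), shift = -350,
                      seed = 11)
  lv <- fit_loadings(mb$gmv, mb$labels, top_k = 4)
  px <- reweight_gmv(mb$gmv, lv)
  y <- as.numeric(mb$labels[px$subject] == 3)
  expect_gt(cor(px$score, y), 0.1)  # point-biserial positive by construction
})

test_that("proxy validation matches a direct covariance oracle", {
  set.seed(12)
  n <- 300
  px <- data.frame(subject = sprintf("V%03d", 1:n), score = rnorm(n))
  out <- data.frame(subject = px$subject,
                    neg = -px$score + rnorm(n, 0, 0.5),
                    indep = rnorm(n))
  val <- validate_proxy(px, out)
  r_neg <- val$r[val$outcome == "neg"]
  expect_lt(r_neg, -0.7)
  expect_lt(val$p_adj[val$outcome == "neg"], 1e-10)
  expect_lt(abs(val$r[val$outcome == "indep"]), 3 / sqrt(n))
  # direct covariance-formula oracle (residualization = centering here)
  s <- px$score - mean(px$score); y <- out$neg - mean(out$neg)
  r_ref <- sum(s * y) / sqrt(sum(s^2) * sum(y^2))
  expect_equal(r_neg, r_ref, tolerance = 1e-12)
  expect_error(validate_proxy(px[1:5, ], out), "shared")
})

test_that("top-k selection recovers a known loaded ROI subset", {
  # group-3 membership loads on a known 10-ROI subset; the rest are null
  set.seed(13)
  n <- 1500
  g <- stats::setNames(c(rep(1, 690), rep(2, 745), rep(3, 65)),
                       sprintf("K%04d", 1:n))
  G <- matrix(rnorm(n * 44, 5000, 300), n, 44,
              dimnames = list(NULL, sprintf("roi%02d", 1:44)))
  loaded <- sprintf("roi%02d", seq(3, 30, 3))  # 10 known ROIs
  G[g == 3, loaded] <- G[g == 3, loaded] - 250
  lv <- fit_loadings(data.frame(subject = names(g), G, check.names = FALSE),
                     g, top_k = 10)
  expect_gte(length(intersect(lv$selected, loaded)), 8)
})
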