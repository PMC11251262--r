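ref_quadratic <- function(n = 400, noise = 0, peak = 13.5, height = 5e5,
                          curv = 800, seed = 5, offset2 = 0) {
  set.seed(seed)
  age <- runif(n, 5, 25)
  study <- rep(c("ref1", "ref2"), length.out = n)
  data.frame(subject = sprintf("R%04d", 1:n), age = age,
             sex = sample(c("F", "M"), n, TRUE), study = study,
             icv = rlnorm(n, log(1.5e6), 0.05),
             total_gmv = height - curv * (age - peak)^2 +
               offset2 * (study == "ref2") + rnorm(n, 0, noise))
}

test_that("reference curve recovers a noise-free quadratic exactly", {
  ref <- ref_quadratic(noise = 0)
  rc <- fit_reference_curve(ref)
  ages <- seq(6, 24, 2)
  expect_equal(predict(rc, ages), 5e5 - 800 * (ages - 13.5)^2, tolerance = 1e-6)
  expect_error(predict(rc, 40), "domain")
})

test_that("a pure study offset is absorbed by the study term", {
  ref <- ref_quadratic(noise = 0, offset2 = 250)
  rc <- fit_reference_curve(ref)
  expect_equal(unname(rc$coefs["studyref2"]), 250, tolerance = 1e-6)
  # curve shape unchanged: second derivative equals the generating curvature
  expect_equal(unname(rc$coefs["age2"]), -800, tolerance = 1e-8)
})

test_that("noisy quadratic fit stays within 3 pointwise SEs of truth", {
  ref <- ref_quadratic(n = 2000, noise = 3000, seed = 6)
  rc <- fit_reference_curve(ref)
  ages <- seq(6, 24, 3)
  truth <- 5e5 - 800 * (ages - 13.5)^2
  # pointwise SE from the OLS covariance (oracle computed directly)
  X <- cbind(1, ref$age, ref$age^2, ref$study == "ref2")
  XtXi <- solve(crossprod(X))
  for (i in seq_along(ages)) {
    x0 <- c(1, ages[i], ages[i]^2, 0.5)
    se <- 3000 * sqrt(drop(t(x0) %*% XtXi %*% x0))
    expect_lt(abs(predict(rc, ages[i]) - truth[i]), 3 * se + 1e-9)
  }
})

make_long_cohort <- function(n = 150, dev_slope = c(0, 0, 0), noise = 0,
                             seed = 9, peak = 13.5, height = 5e5, curv = 800) {
  set.seed(seed)
  g <- rep(1:3, length.out = n)
  rows <- expand.grid(subject = sprintf("L%03d", 1:n), age = c(14, 19, 23),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[order(rows$subject), ]
  gi <- g[match(rows$subject, sprintf("L%03d", 1:n))]
  rows$sex <- "F"; rows$site <- "site1"
  rows$icv <- 1.5e6
  rows$total_gmv <- height - curv * (rows$age - peak)^2 +
    dev_slope[gi] * (rows$age - 18.5) + rnorm(nrow(rows), 0, noise)
  list(scans = rows, labels = stats::setNames(g, sprintf("L%03d", 1:n)))
}

test_that("cohort identical to the reference has near-zero deviation curves", {
  ref <- ref_quadratic(noise = 0)
  rc <- fit_reference_curve(ref)
  ch <- make_long_cohort(noise = 0)
  gc <- fit_group_deviation_curves(ch$scans, ch$labels, rc,
                                   covariates = character(0))
  expect_lt(max(abs(gc$curves$fit - (5e5 - 800 * (gc$curves$age - 13.5)^2))),
            1e-4)
})

test_that("a planted group deviation slope is recovered", {
  ref <- ref_quadratic(n = 1500, noise = 1000, seed = 10)
  rc <- fit_reference_curve(ref)
  ch <- make_long_cohort(n = 300, dev_slope = c(0, 0, 2000), noise = 1000,
                         seed = 11)
  gc <- fit_group_deviation_curves(ch$scans, ch$labels, rc,
                                   covariates = character(0))
  r15 <- growth_rate(gc, 15, rate_eps = 1)
  diff31 <- r15$rate[r15$group == 3] - r15$rate[r15$group == 1]
  expect_lt(abs(diff31 - 2000), 200)
})

test_that("growth rates match finite differences and classify signs", {
  ref <- ref_quadratic(noise = 0, peak = 15)
  rc <- fit_reference_curve(ref)
  ch <- make_long_cohort(noise = 0, peak = 15)
  gc <- fit_group_deviation_curves(ch$scans, ch$labels, rc,
                                   covariates = character(0))
  r <- growth_rate(gc, c(10, 15, 20), rate_eps = 5)
  r1 <- r[r$group == 1, ]
  expect_equal(r1$classification, c("increase", "stable", "decrease"))
  expect_lt(abs(r1$rate[2]), 5)
  # finite-difference oracle on the fitted curve
  cv <- gc$curves[gc$curves$group == 1, ]
  for (a in c(10, 20)) {
    i <- which(abs(cv$age - a) < 1e-9)
    fd <- (cv$fit[i + 1] - cv$fit[i - 1]) / (cv$age[i + 1] - cv$age[i - 1])
    expect_lt(abs(r1$rate[r1$age == a] - fd), 1e-6 * max(1, abs(fd)) + 0.5)
  }
  expect_error(growth_rate(gc, 40), "domain")
})

test_that("two-stage peak estimation locates a parabolic vertex", {
  ref <- ref_quadratic(n = 600, noise = 500, seed = 12)
  ch <- make_long_cohort(n = 200, noise = 500, seed = 13)
  pk <- estimate_peak(ch$scans, ref, ch$labels, gmv_basis_df = 8)
  expect_true(all(abs(pk$peaks$peak_age - 13.5) < 0.5))
  expect_true(all(abs(pk$peaks$peak_gmv - 5e5) < 5000))
  expect_false(any(pk$peaks$boundary))
  expect_equal(nrow(pk$subject_peaks), 200)
})

test_that("monotone data peaks at the boundary with a warning", {
  ref <- ref_quadratic(n = 300, noise = 100, seed = 14, peak = 40, curv = 300)
  ch <- make_long_cohort(n = 80, noise = 100, seed = 15, peak = 40, curv = 300)
  expect_warning(pk <- estimate_peak(ch$scans, ref, ch$labels,
                                     gmv_basis_df = 6), "boundary")
  expect_true(all(pk$peaks$boundary))
})

test_that("a vertical offset between groups shifts peak GMV, not peak age", {
  ref <- ref_quadratic(n = 600, noise = 200, seed = 16)
  ch <- make_long_cohort(n = 200, noise = 200, seed = 17)
  delta <- 8000
  g2 <- names(ch$labels)[ch$labels == 2]
  ch$scans$total_gmv <- ch$scans$total_gmv +
    delta * (ch$scans$subject %in% g2)
  pk <- estimate_peak(ch$scans, ref, ch$labels, gmv_basis_df = 8)
  p <- pk$peaks
  expect_lt(abs(p$peak_age[p$group == 2] - p$peak_age[p$group == 1]), 0.6)
  expect_lt(abs((p$peak_gmv[p$group == 2] - p$peak_gmv[p$group == 1]) - delta),
            1500)
})
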