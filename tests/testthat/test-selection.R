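# Selection metrics: relativization, opportunity for (sexual) selection,
# gradient regressions, the PCA reparametrization and slope comparisons.

test_that("relativization divides by the cohort mean", {
  expect_equal(relativize(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(relativize(5), 1)
  set.seed(3)
  for (r in 1:10) {
    v <- rexp(sample(2:40, 1))
    expect_equal(mean(relativize(v)), 1)
  }
  expect_warning(z <- relativize(c(0, 0, 0)), "zero")
  expect_equal(z, c(0, 0, 0))
})

test_that("opportunity for selection is the variance over squared mean", {
  expect_equal(opportunity_for_selection(c(3, 3, 3)), 0)
  expect_equal(opportunity_for_selection(c(1, 2, 3)), 0.25)
  expect_equal(opportunity_for_sexual_selection(c(1, 3)), 0.5)
  # brute-force identity and scale invariance on random vectors
  set.seed(8)
  for (r in 1:25) {
    v <- rlnorm(sample(2:50, 1))
    expect_equal(opportunity_for_selection(v), var(v) / mean(v)^2)
    expect_equal(opportunity_for_selection(3.7 * v),
                 opportunity_for_selection(v))
    # relativized input: I equals the plain sample variance
    expect_equal(opportunity_for_selection(relativize(v)),
                 var(relativize(v)))
  }
  expect_error(opportunity_for_selection(5), "n >= 2")
})

test_that("bootstrap intervals behave on degenerate and random data", {
  ci0 <- bootstrap_ci(opportunity_for_selection, rep(2, 10), reps = 200,
                      seed = 1)
  expect_equal(unname(ci0), c(0, 0))
  # the interval for the mean contains the point estimate
  set.seed(21)
  for (r in 1:50) {
    v <- rgamma(sample(5:30, 1), 2)
    ci <- bootstrap_ci(mean, v, reps = 200, seed = r)
    expect_lte(ci[["lower"]], mean(v))
    expect_gte(ci[["upper"]], mean(v))
  }
  # identical seeds give identical intervals
  v <- rlnorm(20)
  expect_identical(bootstrap_ci(var, v, reps = 150, seed = 9),
                   bootstrap_ci(var, v, reps = 150, seed = 9))
})

test_that("bootstrap interval coverage for I is near nominal", {
  # lognormal reproductive success with known I = exp(sigma^2) - 1
  sigma <- 0.3
  true_I <- exp(sigma^2) - 1
  set.seed(14)
  cover <- vapply(1:400, function(r) {
    v <- rlnorm(25, 0, sigma)
    ci <- bootstrap_ci(opportunity_for_selection, v, reps = 300, seed = r)
    ci[["lower"]] <= true_I && true_I <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(cover), 0.84)
  expect_lte(mean(cover), 0.99)
})

test_that("bivariate gradients equal closed-form least squares", {
  g <- bivariate_gradient(c(1, 2, 3), c(2, 4, 6), "beta_mm")
  expect_equal(g$slope, 2)
  expect_equal(g$r2, 1)
  # independent response: slope statistically indistinguishable from zero
  set.seed(17)
  x <- rnorm(1000); y <- rnorm(1000)
  g0 <- bivariate_gradient(x, y)
  expect_lt(abs(g0$slope), 3 * g0$se)
  # full agreement with stats::lm on random data (the independent oracle)
  for (r in 1:20) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    g <- bivariate_gradient(x, y)
    lf <- summary(lm(y ~ x))
    expect_equal(g$slope, cov(x, y) / var(x))
    expect_equal(g$slope, unname(lf$coefficients[2, 1]))
    expect_equal(g$se, unname(lf$coefficients[2, 2]))
    expect_equal(g$t, unname(lf$coefficients[2, 3]))
    expect_equal(g$p, unname(lf$coefficients[2, 4]))
    expect_equal(g$r2, lf$r.squared)
  }
  expect_error(bivariate_gradient(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(bivariate_gradient(1:2, 1:2), "n >= 3")
})

test_that("multiple regression separates within- and cross-sex gradients", {
  msm <- c(1, 2, 3, 4, 5); msf <- c(2, 1, 4, 3, 5)
  rs <- 2 * msm + 0 * msf
  g <- suppressWarnings(multivariate_gradients(msm, msf, rs, "male"))
  expect_equal(g$within$slope, 2, tolerance = 1e-12)
  expect_equal(g$cross$slope, 0, tolerance = 1e-12)
  expect_equal(g$within$label, "beta_mm")
  expect_equal(g$cross$label, "beta_mf")
  # against the normal equations on random data
  set.seed(23)
  for (r in 1:20) {
    n <- sample(6:40, 1)
    a <- rnorm(n); b <- rnorm(n); y <- rnorm(n)
    X <- cbind(1, a, b)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    g <- multivariate_gradients(a, b, y, "female")
    expect_equal(g$cross$slope, beta[2], tolerance = 1e-9)   # on MS_m
    expect_equal(g$within$slope, beta[3], tolerance = 1e-9)  # on MS_f
  }
  # a simulated cross-sex cost is recovered
  set.seed(29)
  msm <- rnorm(200, 5); msf <- rnorm(200, 5)
  rs <- 1.5 * msm - 0.8 * msf + rnorm(200, 0, 0.5)
  g <- multivariate_gradients(msm, msf, rs, "male")
  expect_lt(abs(g$cross$slope - (-0.8)), 3 * g$cross$se)
  # collinear predictors point to the PCA route
  expect_error(multivariate_gradients(1:5, 2 * (1:5), rnorm(5)),
               "principal-component")
})

test_that("the mating-success PCA satisfies its algebraic identities", {
  set.seed(41)
  for (r in 1:10) {
    n <- sample(10:50, 1)
    a <- relativize(rgamma(n, 4)); b <- relativize(rgamma(n, 4))
    p <- mating_pca(a, b)
    L <- p$loadings
    expect_equal(t(L) %*% L, diag(2), tolerance = 1e-12,
                 ignore_attr = TRUE)                     # orthonormal
    expect_equal(sum(p$eigenvalues), 2, tolerance = 1e-12)
    expect_equal(cor(p$scores[, 1], p$scores[, 2]), 0, tolerance = 1e-10)
    # labels follow the loading signs
    expect_true(all(L[, "activity"] > 0))
    expect_equal(prod(sign(L[, "bias"])), -1)
    expect_gt(L["rel_MS_f", "bias"], 0)  # female bias scores positive
  }
  # perfectly correlated columns: activity carries everything
  a <- c(1, 2, 3, 4); b <- 2 * a
  p <- mating_pca(a, b)
  expect_equal(unname(p$loadings[, "activity"]), rep(1 / sqrt(2), 2))
  expect_equal(unname(p$eigenvalues), c(2, 0), tolerance = 1e-12)
  expect_error(mating_pca(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("gradients on PC scores reproduce the two-predictor fit", {
  set.seed(47)
  n <- 30
  msm <- relativize(rgamma(n, 5)); msf <- relativize(rgamma(n, 5))
  rs <- relativize(rgamma(n, 3))
  p <- mating_pca(msm, msf)
  g <- pc_gradients(p, rs, "male")
  # orthogonal regressors: joint fit coefficients equal the bivariate slopes
  joint <- lm(rs ~ p$scores[, "bias"] + p$scores[, "activity"])
  expect_equal(g$PC1$slope, unname(coef(joint)[2]), tolerance = 1e-9)
  expect_equal(g$PC2$slope, unname(coef(joint)[3]), tolerance = 1e-9)
  # rotation invariance: fitted values equal those from the standardized MS
  direct <- lm(rs ~ scale(msm) + scale(msf))
  expect_equal(unname(fitted(joint)), unname(fitted(direct)),
               tolerance = 1e-9)
  expect_equal(g$PC1$label, "beta_mPC1")
  # a female-biased mating cost on male success shows up as beta_mPC1 < 0
  set.seed(53)
  hits <- vapply(1:100, function(r) {
    msm <- relativize(rgamma(25, 5)); msf <- relativize(rgamma(25, 5))
    rs <- pmax(0, 1 + 1 * msm - 1 * msf + rnorm(25, 0, 0.3))
    p <- mating_pca(msm, msf)
    pc_gradients(p, relativize(rs), "male")$PC1$slope < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("slope comparisons use the pooled-SE t statistic", {
  set.seed(59)
  x1 <- rnorm(20); y1 <- 2 * x1 + rnorm(20, 0, 0.01)
  x2 <- rnorm(25); y2 <- 3 * x2 + rnorm(25, 0, 0.01)
  f1 <- bivariate_gradient(x1, y1); f2 <- bivariate_gradient(x2, y2)
  cmp <- compare_slopes(f1, f2)
  expect_equal(cmp[["t"]],
               (f1$slope - f2$slope) / sqrt(f1$se^2 + f2$se^2))
  expect_equal(cmp[["df"]], 20 + 25 - 4)
  expect_lt(cmp[["p"]], 1e-6)
  same <- compare_slopes(f1, f1)
  expect_equal(same[["t"]], 0)
  expect_equal(same[["p"]], 1)
})

test_that("the weekly report flags degenerate weeks instead of dropping them", {
  rec <- data.frame(focal_id = rep(c("a", "b", "c", "d"), 2),
                    week = rep(1:2, each = 4),
                    MS_m = 2, MS_f = 2, RS_f = 100, RS_m = 50, alive = TRUE)
  fit <- suppressWarnings(fit_sexual_selection(rec, bootstrap_reps = 100))
  expect_equal(fit$metrics$I_sm, c(0, 0))
  expect_true(all(grepl("constant|PCA", fit$flagged$reason)))
  expect_null(fit$gradients)
})

test_that("a full simulated experiment yields positive male gradients", {
  rec <- small_experiment()$records
  fit <- fit_sexual_selection(rec, bootstrap_reps = 150, seed = 5)
  bm <- fit$gradients[fit$gradients$label == "beta_mm", ]
  expect_equal(nrow(bm), 4)
  expect_true(all(bm$slope > 0))
  # summary/coef/print accessors work
  expect_s3_class(summary(fit), "summary.sexsel_fit")
  cf <- coef(fit)
  expect_true("beta_mm" %in% names(cf))
  expect_output(print(fit), "Weekly sexual-selection analysis")
  cmp <- slope_comparison_table(fit, "beta_mm")
  expect_equal(nrow(cmp), choose(4, 2))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})
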