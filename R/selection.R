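# Selection metrics: relative fitness, opportunity for (sexual) selection,
# within- and cross-sex selection gradients by bivariate and multiple
# regression, principal-component reparametrization, bootstrap CIs, and
# between-week slope comparisons.

#' Relativize fitness values
#'
#' Divides each value by the cohort mean, giving relative (mean-1) fitness as
#' used throughout the selection analyses. A cohort with zero mean yields an
#' all-zero vector with a warning (such weeks are dropped from gradient fits).
#'
#' @param values non-negative fitness or mating-success values.
#' @return values divided by their mean.
#' @export
relativize <- function(values) {
  if (!length(values)) stop("empty cohort")
  m <- mean(values)
  if (m == 0) {
    warning("cohort mean is zero: relative values undefined, returning zeros")
    return(rep(0, length(values)))
  }
  values / m
}

#' Opportunity for selection
#'
#' The variance-standardized fitness measure `I`: sample variance of
#' reproductive success divided by its squared mean. For relativized (mean-1)
#' input this equals the sample variance. `I` bounds the strength of selection
#' from above and is scale invariant.
#'
#' @param values reproductive-success values (n >= 2).
#' @return non-negative real.
#' @export
opportunity_for_selection <- function(values) {
  if (length(values) < 2) stop("opportunity for selection needs n >= 2")
  m <- mean(values)
  if (m == 0) stop("undefined: mean is zero")
  stats::var(values) / m^2
}

#' Opportunity for sexual selection
#'
#' The same variance-standardized measure applied to mating success (`I_s`).
#'
#' @param values mating-success values (n >= 2).
#' @return non-negative real.
#' @export
opportunity_for_sexual_selection <- function(values) {
  opportunity_for_selection(values)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the data (vector elements, or data-frame rows) with replacement
#' and returns the percentile interval of the statistic. Resamples on which
#' the statistic is undefined are redrawn, at most ten times each.
#'
#' @param statistic function of one resample.
#' @param data vector or data frame of focal-level data.
#' @param reps number of bootstrap resamples (>= 100).
#' @param seed RNG seed for the resampling.
#' @param conf_level interval coverage (default 0.95).
#' @return named vector `lower`, `upper`.
#' @export
bootstrap_ci <- function(statistic, data, reps = 1000L, seed = 1L,
                         conf_level = 0.95) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2) stop("bootstrap needs n >= 2")
  if (reps < 100) stop("use at least 100 bootstrap resamples")
  take <- function(idx) if (is.data.frame(data)) data[idx, , drop = FALSE]
  else data[idx]
  stat <- with_substream(seed, {
    vapply(seq_len(reps), function(r) {
      for (attempt in 1:10) {
        val <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                        error = function(e) NA_real_)
        if (is.finite(val)) return(val)
      }
      stop("statistic undefined on 10 consecutive resamples")
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1], upper = q[2])
}

# Closed-form simple OLS with the usual t-based inference; the workhorse
# behind every bivariate gradient (kept closed-form so bootstrap loops stay
# cheap). Cross-checked against stats::lm in the test suite.
ols_simple <- function(x, y) {
  n <- length(x)
  vx <- stats::var(x)
  slope <- stats::cov(x, y) / vx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  df <- n - 2L
  s2 <- sum(res^2) / df
  se <- sqrt(s2 / (vx * (n - 1)))
  tval <- slope / se
  ssy <- sum((y - mean(y))^2)
  r2 <- if (ssy > 0) 1 - sum(res^2) / ssy else NA_real_
  list(slope = slope, intercept = intercept, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), n = n, r2 = r2)
}

#' Bivariate selection gradient
#'
#' Least-squares regression slope of relative reproductive success on relative
#' mating success — the sexual selection gradient (`beta_mm`, `beta_ff`) or,
#' with the other role's mating success as predictor, the cross-sex gradient
#' (`beta_mf`, `beta_fm`).
#'
#' @param rel_MS relative mating success (predictor).
#' @param rel_RS relative reproductive success (response).
#' @param label gradient label stored on the fit.
#' @return an object of class `"gradient_fit"`: `label`, `slope`, `intercept`,
#'   `se`, `t`, `p`, `n`, `r2`.
#' @export
bivariate_gradient <- function(rel_MS, rel_RS, label = "beta") {
  if (length(rel_MS) != length(rel_RS)) stop("unequal lengths")
  if (length(rel_MS) < 3) stop("gradient needs n >= 3")
  if (stats::var(rel_MS) == 0) stop("degenerate fit: constant predictor")
  fit <- ols_simple(rel_MS, rel_RS)
  structure(c(list(label = label), fit), class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("%s: slope %.4f (SE %.4f), t = %.3f, p = %.4g, n = %d, R2 = %.3f\n",
              x$label, x$slope, x$se, x$t, x$p, x$n, x$r2))
  invisible(x)
}

#' Within- and cross-sex gradients by multiple regression
#'
#' Two-predictor least-squares regression of one role's relative reproductive
#' success on both roles' relative mating success, separating the within-sex
#' gradient from the cross-sex gradient while conditioning on the other
#' predictor.
#'
#' @param rel_MS_m,rel_MS_f relative male- and female-role mating success.
#' @param rel_RS relative reproductive success of the chosen perspective.
#' @param perspective `"male"` (response is `RS_m`; within = `beta_mm`, cross
#'   = `beta_mf`) or `"female"` (response `RS_f`; within = `beta_ff`, cross =
#'   `beta_fm`).
#' @return list of two `"gradient_fit"` objects, `within` and `cross`.
#' @export
multivariate_gradients <- function(rel_MS_m, rel_MS_f, rel_RS,
                                   perspective = c("male", "female")) {
  perspective <- match.arg(perspective)
  n <- length(rel_RS)
  if (n < 4) stop("multiple regression needs n >= 4")
  X <- cbind(1, rel_MS_m, rel_MS_f)
  if (qr(X)$rank < 3) {
    stop(paste("collinear mating-success predictors (rank-deficient design):",
               "use the principal-component route (mating_pca)"))
  }
  fit <- stats::lm(rel_RS ~ rel_MS_m + rel_MS_f)
  sm <- summary(fit)$coefficients
  df <- n - 3L
  mk <- function(row, label) {
    structure(list(label = label, slope = sm[row, 1],
                   intercept = stats::coef(fit)[[1]], se = sm[row, 2],
                   t = sm[row, 3], p = sm[row, 4], n = n,
                   r2 = summary(fit)$r.squared),
              class = "gradient_fit")
  }
  if (perspective == "male") {
    list(within = mk("rel_MS_m", "beta_mm"), cross = mk("rel_MS_f", "beta_mf"))
  } else {
    list(within = mk("rel_MS_f", "beta_ff"), cross = mk("rel_MS_m", "beta_fm"))
  }
}

#' Principal-component reparametrization of mating success
#'
#' Eigen-decomposition of the 2x2 correlation matrix of relative male- and
#' female-role mating success, replacing the two (possibly collinear)
#' predictors by two orthogonal components labelled semantically: the
#' component with same-sign loadings is the overall mating *activity*, the one
#' with opposite-sign loadings the sexual *bias* (labels follow the loading
#' pattern, not the eigenvalue order). The bias component's sign is fixed so
#' that it increases with female-biased mating (`MS_f > MS_m`).
#'
#' @param rel_MS_m,rel_MS_f relative mating-success vectors (non-constant).
#' @return an object of class `"mating_pca"`: orthonormal `loadings` (columns
#'   `activity`, `bias` over the standardized MS columns), `eigenvalues`
#'   (summing to 2), and per-focal `scores`.
#' @export
mating_pca <- function(rel_MS_m, rel_MS_f) {
  if (length(rel_MS_m) < 3) stop("PCA needs n >= 3")
  if (stats::var(rel_MS_m) == 0 || stats::var(rel_MS_f) == 0) {
    stop("degenerate PCA: constant mating-success column")
  }
  r <- stats::cor(rel_MS_m, rel_MS_f)
  C <- matrix(c(1, r, r, 1), 2, 2)
  eig <- eigen(C, symmetric = TRUE)
  vals <- eig$values
  vecs <- eig$vectors
  same_sign <- apply(vecs, 2, function(v) prod(sign(v)) >= 0)
  # correlation-matrix eigenvectors are (1,1)/sqrt(2) and (1,-1)/sqrt(2);
  # identify components by their loading pattern
  act_col <- which(same_sign)[1]
  bias_col <- which(!same_sign)[1]
  act <- vecs[, act_col]
  if (sum(act) < 0) act <- -act
  bias <- vecs[, bias_col]
  if (bias[2] < 0) bias <- -bias  # positive loading on MS_f: female bias
  Z <- cbind(scale(rel_MS_m)[, 1], scale(rel_MS_f)[, 1])
  loadings <- cbind(activity = act, bias = bias)
  rownames(loadings) <- c("rel_MS_m", "rel_MS_f")
  scores <- Z %*% loadings
  structure(list(loadings = loadings,
                 eigenvalues = c(activity = vals[act_col],
                                 bias = vals[bias_col]),
                 scores = scores, correlation = r),
            class = "mating_pca")
}

#' @export
print.mating_pca <- function(x, ...) {
  cat("PCA of relative mating success (correlation matrix)\n")
  cat(sprintf("  cor(MS_m, MS_f) = %.3f\n", x$correlation))
  cat(sprintf("  activity: eigenvalue %.3f, loadings (%.3f, %.3f)\n",
              x$eigenvalues["activity"], x$loadings[1, "activity"],
              x$loadings[2, "activity"]))
  cat(sprintf("  bias:     eigenvalue %.3f, loadings (%.3f, %.3f)\n",
              x$eigenvalues["bias"], x$loadings[1, "bias"],
              x$loadings[2, "bias"]))
  invisible(x)
}

#' Gradients on principal-component scores
#'
#' Bivariate least-squares gradients of relative reproductive success on the
#' two mating-success principal components. Because the scores are orthogonal,
#' the two bivariate slopes equal the coefficients of the joint two-predictor
#' fit, and the fitted values of a regression on both components reproduce
#' those of the regression on both standardized mating-success columns.
#' Components are reported under the emulated study's convention: PC1 is the
#' sexual bias, PC2 the overall mating activity.
#'
#' @param pca a `"mating_pca"`.
#' @param rel_RS relative reproductive success (paired with the scores).
#' @param perspective `"male"` or `"female"` (labels only).
#' @return list of two `"gradient_fit"` objects, `PC1` (bias) and `PC2`
#'   (activity).
#' @export
pc_gradients <- function(pca, rel_RS, perspective = c("male", "female")) {
  perspective <- match.arg(perspective)
  pfx <- if (perspective == "male") "beta_m" else "beta_f"
  list(PC1 = bivariate_gradient(pca$scores[, "bias"], rel_RS,
                                paste0(pfx, "PC1")),
       PC2 = bivariate_gradient(pca$scores[, "activity"], rel_RS,
                                paste0(pfx, "PC2")))
}

#' Compare two regression slopes
#'
#' Two-sample t-test for equality of two independent regression slopes:
#' `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)` on `n1 + n2 - 4` degrees of freedom,
#' as used to compare weekly gradient estimates.
#'
#' @param fit1,fit2 `"gradient_fit"` objects from independent samples.
#' @return named vector `t`, `df`, `p`.
#' @export
compare_slopes <- function(fit1, fit2) {
  if (!inherits(fit1, "gradient_fit") || !inherits(fit2, "gradient_fit")) {
    stop("compare_slopes expects two gradient fits")
  }
  if (!is.finite(fit1$se) || !is.finite(fit2$se) || fit1$se <= 0 ||
      fit2$se <= 0) {
    stop("degenerate fit: slope standard error unavailable")
  }
  tval <- (fit1$slope - fit2$slope) / sqrt(fit1$se^2 + fit2$se^2)
  df <- fit1$n + fit2$n - 4L
  c(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}
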