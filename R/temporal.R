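# Temporal inference: repeated-measures linear mixed models testing whether
# the selection gradients change across cumulative weeks, the mating-mode
# (reciprocity) model, and Tukey post-hoc week comparisons.

#' Specify a weekly repeated-measures mixed model
#'
#' Describes a Gaussian linear mixed model with week as a categorical fixed
#' factor, continuous covariates with their week interactions, and a random
#' intercept per focal (the repeated factor).
#'
#' @param response response column name.
#' @param covariates continuous fixed-effect column names.
#' @param week_col categorical week column (treated as a factor).
#' @param focal_col grouping column for the random intercept.
#' @param interactions include covariate-by-week interactions?
#' @return an object of class `"mixed_model_spec"`.
#' @export
mixed_model_spec <- function(response, covariates = character(),
                             week_col = "week", focal_col = "focal_id",
                             interactions = TRUE) {
  structure(list(response = response, covariates = covariates,
                 week_col = week_col, focal_col = focal_col,
                 interactions = isTRUE(interactions)),
            class = "mixed_model_spec")
}

spec_formula <- function(spec, random = TRUE) {
  wk <- "week_f"
  fixed <- if (length(spec$covariates)) {
    op <- if (spec$interactions) " * " else " + "
    paste(vapply(spec$covariates, function(v) paste0(v, op, wk), character(1)),
          collapse = " + ")
  } else wk
  rhs <- if (random) paste0(fixed, " + (1 | ", spec$focal_col, ")") else fixed
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit a weekly repeated-measures mixed model
#'
#' REML linear mixed model with a random intercept per focal, returning
#' marginal (type III) F-tests with Satterthwaite-approximated denominator
#' degrees of freedom for every fixed term, plus the REML variance components.
#' If the mixed fit fails to converge to a usable solution, the model falls
#' back to ordinary least squares (random-effect variance 0) with a warning;
#' by construction the two agree whenever the between-focal variance is
#' estimated as zero.
#'
#' @param data long-format data frame (one row per focal per week).
#' @param spec a [mixed_model_spec()].
#' @return list with `tests` (term, F, df1, df2, p), `varcomp` (named variance
#'   components), `singular` flag, `fallback` flag and the underlying `model`.
#' @export
fit_weekly_mixed_model <- function(data, spec) {
  data$week_f <- factor(data[[spec$week_col]])
  n_focal <- length(unique(data[[spec$focal_col]]))
  if (n_focal < 2) stop("mixed model needs >= 2 focals")
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(spec_formula(spec, random = TRUE),
                                    data = data, REML = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    at <- tryCatch(stats::anova(fit, type = 3, ddf = "Satterthwaite"),
                   error = function(e) NULL)
  }
  if (is.null(fit) || is.null(at)) {
    warning("mixed model fit failed; falling back to ordinary regression")
    return(ols_anova_fallback(data, spec))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  tests <- data.frame(term = gsub("week_f", "Week", rownames(at)),
                      F = at$`F value`,
                      df1 = at$NumDF, df2 = at$DenDF, p = at$`Pr(>F)`,
                      stringsAsFactors = FALSE, row.names = NULL)
  list(tests = tests, varcomp = varcomp,
       singular = lme4::isSingular(fit), fallback = FALSE, model = fit)
}

# Ordinary-regression fallback: type III F-tests with sum-to-zero contrasts.
ols_anova_fallback <- function(data, spec) {
  f <- spec_formula(spec, random = FALSE)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(f, data = data)
  at <- car::Anova(fit, type = 3)
  keep <- !rownames(at) %in% c("(Intercept)", "Residuals")
  tests <- data.frame(term = gsub("week_f", "Week", rownames(at)[keep]),
                      F = at$`F value`[keep],
                      df1 = at$Df[keep],
                      df2 = stats::df.residual(fit),
                      p = at$`Pr(>F)`[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(tests = tests, varcomp = c(focal = 0, Residual = summary(fit)$sigma^2),
       singular = TRUE, fallback = TRUE, model = fit)
}

#' Mating-mode (reciprocity) model
#'
#' Mixed model of cumulative female mating success on cumulative male mating
#' success and week, with a random intercept per focal. In a unilateral mating
#' system the male-mating-success term is non-significant: copulating in one
#' role does not oblige the partner roles to alternate. A significant positive
#' term is the signature of (relaxed) reciprocity.
#'
#' @param records success records with `MS_m`, `MS_f`, `week`, `focal_id`.
#' @return as [fit_weekly_mixed_model()].
#' @export
mating_mode_model <- function(records) {
  fit_weekly_mixed_model(records,
                         mixed_model_spec("MS_f", covariates = "MS_m"))
}

#' Quality-correlation model
#'
#' Mixed model of female reproductive success on male reproductive success and
#' week (random intercept per focal); a persistent positive association would
#' indicate overall individual quality driving both roles' success.
#'
#' @param records success records with `RS_m`, `RS_f`, `week`, `focal_id`.
#' @return as [fit_weekly_mixed_model()].
#' @export
quality_correlation_model <- function(records) {
  fit_weekly_mixed_model(records,
                         mixed_model_spec("RS_f", covariates = "RS_m"))
}

#' Tukey post-hoc comparisons between weeks
#'
#' All pairwise differences between week levels of a fitted (mixed) model,
#' with Tukey-adjusted p-values, plus a compact letter display in which levels
#' sharing a letter do not differ at the chosen level.
#'
#' @param model a fitted model from [fit_weekly_mixed_model()] (the `model`
#'   element) or any model `emmeans` understands.
#' @param factor name of the factor term (default the week factor).
#' @param alpha significance level for the letter display.
#' @return list with `comparisons` (contrast, estimate, SE, df, t, p) and
#'   `letters` (named character vector by level).
#' @export
tukey_posthoc <- function(model, factor = "week_f", alpha = 0.05) {
  em <- emmeans::emmeans(model, specs = factor)
  lv <- as.character(as.data.frame(em)[[1]])
  if (length(lv) < 2) stop("post-hoc comparison needs >= 2 factor levels")
  prs <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = "tukey"))
  comparisons <- data.frame(contrast = as.character(prs$contrast),
                            estimate = prs$estimate,
                            se = prs$SE, df = prs$df, t = prs$t.ratio,
                            p = prs$p.value, stringsAsFactors = FALSE)
  # significance matrix from the adjusted p-values; pairwise contrasts are
  # emitted in level order, so map them positionally
  k <- length(lv)
  sig <- matrix(FALSE, k, k, dimnames = list(lv, lv))
  idx <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      idx <- idx + 1L
      s <- prs$p.value[idx] < alpha
      sig[i, j] <- s; sig[j, i] <- s
    }
  }
  list(comparisons = comparisons,
       letters = compact_letters(sig))
}

# Compact letter display by insert-and-absorb on a logical "differs" matrix.
compact_letters <- function(sig) {
  lv <- rownames(sig)
  groups <- list(lv)  # start with one group containing everything
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i || !sig[i, j]) next
      # split every group containing both members
      new_groups <- list()
      for (g in groups) {
        if (lv[i] %in% g && lv[j] %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, lv[i])),
                          list(setdiff(g, lv[j])))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb groups contained in another
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) {
        for (b in seq_along(new_groups)) {
          if (a != b && keep[a] && keep[b] &&
              all(new_groups[[a]] %in% new_groups[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      groups <- new_groups[keep]
    }
  }
  letters_out <- stats::setNames(rep("", length(lv)), lv)
  for (gi in seq_along(groups)) {
    for (m in groups[[gi]]) {
      letters_out[m] <- paste0(letters_out[m], letters[gi])
    }
  }
  letters_out
}
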