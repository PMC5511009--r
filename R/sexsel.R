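# The central model object: weekly opportunity-for-selection statistics and
# the eight selection gradients, fitted to per-focal cumulative success
# records.

GRADIENT_LABELS <- c("beta_mm", "beta_ff", "beta_mf", "beta_fm",
                     "beta_mPC1", "beta_mPC2", "beta_fPC1", "beta_fPC2")

#' Fit weekly sexual-selection metrics and gradients
#'
#' For every cumulative week, relativizes the living focals' mating and
#' reproductive success (per role), computes the opportunity for selection
#' (`I_m`, `I_f`) and for sexual selection (`I_sm`, `I_sf`) with percentile
#' bootstrap confidence intervals, and fits the eight selection gradients:
#' the within-sex gradients `beta_mm` and `beta_ff`, the cross-sex gradients
#' `beta_mf` and `beta_fm` (all bivariate least squares), and the gradients on
#' the two principal components of mating success (`beta_mPC1`, `beta_mPC2`,
#' `beta_fPC1`, `beta_fPC2`; PC1 = sexual bias, PC2 = mating activity). Weeks
#' failing a precondition (fewer than 3 living focals, zero-mean or constant
#' columns) are flagged, not silently dropped.
#'
#' @param records success records from [build_success_records()]: columns
#'   `focal_id`, `week`, `MS_m`, `MS_f`, `RS_f`, `RS_m`, `alive`.
#' @param weeks weeks to analyse (default: all present).
#' @param bootstrap_reps bootstrap resamples for the `I` confidence intervals.
#' @param seed RNG seed for the bootstrap.
#' @param conf_level confidence level of the bootstrap intervals.
#' @return an object of class `"sexsel_fit"` with components `metrics` (one
#'   row per week), `gradients` (one row per gradient per week), `fits` (the
#'   underlying `"gradient_fit"` objects), `pca` (per-week `"mating_pca"`),
#'   `relative` (the per-week relativized records), and `flagged`.
#' @examples
#' cfg <- simulation_config(n_groups_multi = 6, n_pairs_single = 0,
#'                          n_isolated = 0, weeks = 2, seed = 3)
#' xp <- simulate_experiment(cfg)
#' rec <- build_success_records(xp)
#' fit <- fit_sexual_selection(rec, bootstrap_reps = 100)
#' coef(fit)
#' @export
fit_sexual_selection <- function(records, weeks = NULL, bootstrap_reps = 1000L,
                                 seed = 1L, conf_level = 0.95) {
  if (is.null(weeks)) weeks <- sort(unique(records$week))
  metrics <- list(); grads <- list(); fits <- list(); pcas <- list()
  flagged <- list(); rel_all <- list()
  for (w in weeks) {
    sub <- records[records$week == w & records$alive, , drop = FALSE]
    if (nrow(sub) < 3) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(week = w, reason = "fewer than 3 living focals")
      next
    }
    has_rsm <- !anyNA(sub$RS_m)
    means_ok <- mean(sub$MS_m) > 0 && mean(sub$MS_f) > 0 &&
      mean(sub$RS_f) > 0 && (!has_rsm || mean(sub$RS_m) > 0)
    if (!means_ok) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(week = w, reason = "zero-mean success column")
      next
    }
    rel <- data.frame(focal_id = sub$focal_id, week = w,
                      rel_MS_m = relativize(sub$MS_m),
                      rel_MS_f = relativize(sub$MS_f),
                      rel_RS_f = relativize(sub$RS_f),
                      rel_RS_m = if (has_rsm) relativize(sub$RS_m) else NA_real_,
                      stringsAsFactors = FALSE)
    rel_all[[length(rel_all) + 1L]] <- rel

    ci <- function(v, what) {
      bootstrap_ci(function(s) opportunity_for_selection(s), v,
                   reps = bootstrap_reps,
                   seed = substream_seed(seed, paste(what, w)),
                   conf_level = conf_level)
    }
    I_sm <- opportunity_for_sexual_selection(rel$rel_MS_m)
    I_sf <- opportunity_for_sexual_selection(rel$rel_MS_f)
    I_f <- opportunity_for_selection(rel$rel_RS_f)
    I_m <- if (has_rsm) opportunity_for_selection(rel$rel_RS_m) else NA_real_
    ci_sm <- ci(rel$rel_MS_m, "I_sm"); ci_sf <- ci(rel$rel_MS_f, "I_sf")
    ci_f <- ci(rel$rel_RS_f, "I_f")
    ci_m <- if (has_rsm) ci(rel$rel_RS_m, "I_m") else c(NA_real_, NA_real_)
    metrics[[length(metrics) + 1L]] <- data.frame(
      week = w, n = nrow(sub),
      I_m = I_m, I_m_lo = ci_m[1], I_m_hi = ci_m[2],
      I_f = I_f, I_f_lo = ci_f[1], I_f_hi = ci_f[2],
      I_sm = I_sm, I_sm_lo = ci_sm[1], I_sm_hi = ci_sm[2],
      I_sf = I_sf, I_sf_lo = ci_sf[1], I_sf_hi = ci_sf[2])

    wk_fits <- list()
    safe_grad <- function(x, y, label) {
      tryCatch(bivariate_gradient(x, y, label), error = function(e) {
        flagged[[length(flagged) + 1L]] <<-
          data.frame(week = w, reason = paste0(label, ": ", conditionMessage(e)))
        NULL
      })
    }
    if (has_rsm) {
      wk_fits$beta_mm <- safe_grad(rel$rel_MS_m, rel$rel_RS_m, "beta_mm")
      wk_fits$beta_mf <- safe_grad(rel$rel_MS_f, rel$rel_RS_m, "beta_mf")
    }
    wk_fits$beta_ff <- safe_grad(rel$rel_MS_f, rel$rel_RS_f, "beta_ff")
    wk_fits$beta_fm <- safe_grad(rel$rel_MS_m, rel$rel_RS_f, "beta_fm")
    pca <- tryCatch(mating_pca(rel$rel_MS_m, rel$rel_MS_f),
                    error = function(e) {
                      flagged[[length(flagged) + 1L]] <<-
                        data.frame(week = w,
                                   reason = paste0("PCA: ", conditionMessage(e)))
                      NULL
                    })
    if (!is.null(pca)) {
      pcas[[as.character(w)]] <- pca
      if (has_rsm) {
        pm <- pc_gradients(pca, rel$rel_RS_m, "male")
        wk_fits$beta_mPC1 <- pm$PC1; wk_fits$beta_mPC2 <- pm$PC2
      }
      pf <- pc_gradients(pca, rel$rel_RS_f, "female")
      wk_fits$beta_fPC1 <- pf$PC1; wk_fits$beta_fPC2 <- pf$PC2
    }
    fits[[as.character(w)]] <- wk_fits
    for (f in wk_fits) {
      if (is.null(f)) next
      grads[[length(grads) + 1L]] <- data.frame(
        week = w, label = f$label, slope = f$slope, intercept = f$intercept,
        se = f$se, t = f$t, p = f$p, n = f$n, r2 = f$r2,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(
    metrics = if (length(metrics)) do.call(rbind, metrics) else NULL,
    gradients = if (length(grads)) do.call(rbind, grads) else NULL,
    fits = fits, pca = pcas,
    relative = if (length(rel_all)) do.call(rbind, rel_all) else NULL,
    flagged = if (length(flagged)) do.call(rbind, flagged) else
      data.frame(week = integer(), reason = character()),
    weeks = weeks, conf_level = conf_level,
    bootstrap_reps = bootstrap_reps, seed = seed),
    class = "sexsel_fit")
}

#' Weekly selection metrics and gradients report
#'
#' Convenience wrapper around [fit_sexual_selection()] returning plain tables.
#'
#' @inheritParams fit_sexual_selection
#' @return list with `metrics`, `gradients` and `flagged` data frames.
#' @export
weekly_metrics_report <- function(records, weeks = NULL,
                                  bootstrap_reps = 1000L, seed = 1L,
                                  conf_level = 0.95) {
  fit <- fit_sexual_selection(records, weeks, bootstrap_reps, seed, conf_level)
  list(metrics = fit$metrics, gradients = fit$gradients, flagged = fit$flagged)
}

#' Compare one gradient's slope between all pairs of weeks
#'
#' Pairwise t-tests (`compare_slopes`) of a gradient across the fitted weeks.
#' Weekly cohorts overlap (cumulative records of the same focals), so these
#' comparisons are descriptive, as in the emulated study's slope tables.
#'
#' @param fit a `"sexsel_fit"`.
#' @param label one of the eight gradient labels.
#' @return data frame `week1`, `week2`, `t`, `df`, `p`.
#' @export
slope_comparison_table <- function(fit, label = "beta_mm") {
  wk <- names(fit$fits)
  out <- list()
  for (i in seq_along(wk)) {
    for (j in seq_along(wk)) {
      if (j <= i) next
      f1 <- fit$fits[[wk[i]]][[label]]
      f2 <- fit$fits[[wk[j]]][[label]]
      if (is.null(f1) || is.null(f2)) next
      cmp <- compare_slopes(f1, f2)
      out[[length(out) + 1L]] <- data.frame(
        label = label, week1 = as.integer(wk[i]), week2 = as.integer(wk[j]),
        t = cmp[["t"]], df = cmp[["df"]], p = cmp[["p"]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(label = character(), week1 = integer(), week2 = integer(),
               t = numeric(), df = numeric(), p = numeric())
}

#' @export
print.sexsel_fit <- function(x, ...) {
  cat("Weekly sexual-selection analysis\n")
  if (is.null(x$metrics)) {
    cat("  no analysable weeks\n")
    return(invisible(x))
  }
  cat(sprintf("  weeks analysed: %s (n = %d-%d focals)\n",
              paste(x$metrics$week, collapse = ", "),
              min(x$metrics$n), max(x$metrics$n)))
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf("  week %d: I_m = %.3f, I_f = %.3f, I_sm = %.3f, I_sf = %.3f\n",
              last$week, last$I_m, last$I_f, last$I_sm, last$I_sf))
  bm <- x$gradients[x$gradients$label == "beta_mm" &
                      x$gradients$week == last$week, ]
  if (nrow(bm)) {
    cat(sprintf("  week %d beta_mm = %.3f (SE %.3f, p = %.4g)\n",
                last$week, bm$slope, bm$se, bm$p))
  }
  if (nrow(x$flagged)) {
    cat(sprintf("  %d week/gradient combination(s) flagged\n", nrow(x$flagged)))
  }
  invisible(x)
}

#' @export
summary.sexsel_fit <- function(object, ...) {
  structure(list(metrics = object$metrics,
                 gradients = object$gradients,
                 flagged = object$flagged,
                 conf_level = object$conf_level),
            class = "summary.sexsel_fit")
}

#' @export
print.summary.sexsel_fit <- function(x, ...) {
  cat(sprintf("Opportunity for (sexual) selection by week [%g%% bootstrap CIs]\n",
              100 * x$conf_level))
  print(format(x$metrics, digits = 3), row.names = FALSE)
  cat("\nSelection gradients by week\n")
  print(format(x$gradients, digits = 3), row.names = FALSE)
  if (nrow(x$flagged)) {
    cat("\nFlagged weeks\n")
    print(x$flagged, row.names = FALSE)
  }
  invisible(x)
}

#' Extract gradient slopes
#'
#' @param object a `"sexsel_fit"`.
#' @param ... unused.
#' @return data frame of weeks by gradient labels, containing slopes.
#' @export
coef.sexsel_fit <- function(object, ...) {
  g <- object$gradients
  if (is.null(g)) return(NULL)
  wide <- stats::reshape(g[, c("week", "label", "slope")], idvar = "week",
                         timevar = "label", direction = "wide")
  names(wide) <- sub("^slope\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Plot weekly selection gradients
#'
#' Scatter plots of relative reproductive success against relative mating
#' success (or a principal-component score), one panel per analysed week, with
#' the fitted gradient line drawn solid when significant at the 5% level and
#' dashed when a trend (p < 0.10), mirroring the conventions of the emulated
#' study's figures.
#'
#' @param x a `"sexsel_fit"`.
#' @param label which gradient to plot (default `beta_mm`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sexsel_fit <- function(x, label = "beta_mm", ...) {
  g <- x$gradients[x$gradients$label == label, , drop = FALSE]
  if (!nrow(g)) stop(sprintf("no fitted weeks for %s", label))
  axes <- switch(label,
                 beta_mm = c("rel_MS_m", "rel_RS_m"),
                 beta_mf = c("rel_MS_f", "rel_RS_m"),
                 beta_ff = c("rel_MS_f", "rel_RS_f"),
                 beta_fm = c("rel_MS_m", "rel_RS_f"),
                 beta_mPC1 = c("bias", "rel_RS_m"),
                 beta_mPC2 = c("activity", "rel_RS_m"),
                 beta_fPC1 = c("bias", "rel_RS_f"),
                 beta_fPC2 = c("activity", "rel_RS_f"),
                 stop("unknown gradient label"))
  weeks <- g$week
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(weeks)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (w in weeks) {
    rel <- x$relative[x$relative$week == w, , drop = FALSE]
    xv <- if (axes[1] %in% c("bias", "activity")) {
      x$pca[[as.character(w)]]$scores[, axes[1]]
    } else rel[[axes[1]]]
    yv <- rel[[axes[2]]]
    graphics::plot(xv, yv, xlab = axes[1], ylab = axes[2],
                   main = sprintf("week %d", w), pch = 19, ...)
    gi <- g[g$week == w, ]
    if (gi$p < 0.10) {
      graphics::abline(gi$intercept, gi$slope, lty = if (gi$p < 0.05) 1 else 2)
    }
  }
  invisible(x)
}
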