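# Paternity: score genotyped eggs at one microsatellite locus and extrapolate
# each focal's male reproductive success to non-genotyped masses through a
# weighted, overdispersion-corrected binomial regression on the focal's share
# of the mother's female matings.

#' Assign paternity classes to genotyped eggs
#'
#' Each egg carries one maternal and one paternal allele. For every way of
#' explaining one egg allele by the mother, the other allele is a possible
#' paternal allele. An egg is scored `focal` when every possible paternal
#' allele is private to the focal, `nonfocal` when every possible paternal
#' allele is carried by a non-focal partner, and `ambiguous` otherwise. In the
#' emulated design the focal is homozygous for an allele absent from all its
#' partners, so genotyped eggs are scored without ambiguity.
#'
#' @param eggs two-column matrix or data frame of allele labels, one row per
#'   genotyped egg.
#' @param mother length-2 maternal genotype.
#' @param focal length-2 focal (candidate father) genotype.
#' @param partner_alleles alleles carried by non-focal candidate fathers
#'   (including the mother herself, who may self-fertilize). Defaults to every
#'   allele seen in `mother` and `eggs` that the focal does not carry.
#' @return list with counts `n_focal`, `n_nonfocal`, `n_ambiguous` and the
#'   per-egg factor `class`.
#' @examples
#' eggs <- rbind(c("A", "C"), c("A", "B"), c("B", "B"))
#' assign_paternity(eggs, mother = c("A", "B"), focal = c("C", "C"))
#' @export
assign_paternity <- function(eggs, mother, focal, partner_alleles = NULL) {
  eggs <- as.matrix(eggs)
  if (is.null(partner_alleles)) {
    partner_alleles <- setdiff(unique(c(mother, as.vector(eggs))), focal)
  }
  focal_private <- setdiff(focal, partner_alleles)
  cls <- character(nrow(eggs))
  for (i in seq_len(nrow(eggs))) {
    e <- eggs[i, ]
    # possible paternal alleles: the complement of each maternally explainable
    # allele
    pat <- unique(c(if (e[1] %in% mother) e[2], if (e[2] %in% mother) e[1]))
    if (!length(pat)) {
      stop(sprintf(
        "egg %d (%s/%s) shares no allele with mother (%s/%s): corrupt data",
        i, e[1], e[2], mother[1], mother[2]))
    }
    could_focal <- any(pat %in% focal_private)
    could_partner <- any(pat %in% partner_alleles)
    cls[i] <- if (could_focal && !could_partner) "focal"
    else if (could_partner && !could_focal) "nonfocal"
    else "ambiguous"
  }
  cls <- factor(cls, levels = c("focal", "nonfocal", "ambiguous"))
  counts <- table(cls)
  list(n_focal = as.integer(counts[["focal"]]),
       n_nonfocal = as.integer(counts[["nonfocal"]]),
       n_ambiguous = as.integer(counts[["ambiguous"]]),
       class = cls)
}

#' Score all genotyped egg masses of an experiment
#'
#' Applies [assign_paternity()] to every mass with genotyped eggs, using the
#' group's focal as candidate father and the alleles of the other (non-focal)
#' group members as the partner allele set.
#'
#' @param genotypes data frame `mass_id`, `egg_index`, `allele1`, `allele2`.
#' @param masses data frame with `mass_id`, `mother_id`, `group_id`.
#' @param roster data frame with `snail_id`, `group_id`, `allele1`, `allele2`,
#'   `is_focal`.
#' @return data frame `mass_id`, `n_genotyped`, `n_focal`, `n_nonfocal`,
#'   `n_ambiguous`.
#' @export
genotype_samples <- function(genotypes, masses, roster) {
  out <- list()
  for (mid in unique(genotypes$mass_id)) {
    g <- genotypes[genotypes$mass_id == mid, , drop = FALSE]
    mrow <- masses[masses$mass_id == mid, , drop = FALSE]
    grp <- roster[roster$group_id == mrow$group_id, , drop = FALSE]
    mo <- grp[grp$snail_id == mrow$mother_id, , drop = FALSE]
    fo <- grp[grp$is_focal, , drop = FALSE]
    partners <- grp[!grp$is_focal, , drop = FALSE]
    res <- assign_paternity(cbind(g$allele1, g$allele2),
                            mother = c(mo$allele1, mo$allele2),
                            focal = c(fo$allele1, fo$allele2),
                            partner_alleles = unique(c(partners$allele1,
                                                       partners$allele2)))
    out[[length(out) + 1L]] <- data.frame(
      mass_id = mid, n_genotyped = nrow(g), n_focal = res$n_focal,
      n_nonfocal = res$n_nonfocal, n_ambiguous = res$n_ambiguous,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Focal's share of a mother's female matings
#'
#' The proportion of copulations received by `mother_id` (through the given
#' cumulative week) in which `focal_id` was the sperm donor; 0 when the mother
#' received no matings. Shares over all candidate fathers of one mother sum to
#' 1 whenever she mated.
#'
#' @param events data frame with `week`, `donor_id`, `recipient_id`.
#' @param mother_id,focal_id snail identifiers.
#' @param week cumulative week.
#' @return a proportion in `[0, 1]`.
#' @export
female_mating_share <- function(events, mother_id, focal_id, week) {
  rec <- events$recipient_id == mother_id & events$week <= week
  denom <- sum(rec)
  if (denom == 0) return(0)
  sum(rec & events$donor_id == focal_id) / denom
}

#' Build paternity-regression observations
#'
#' One observation per (mother, week) over the genotyped masses of non-focal
#' mothers: the number of focal-fathered eggs `k` out of `n` assignable eggs,
#' and the focal's share `x` of the mother's female matings cumulated through
#' the week the mass was laid.
#'
#' @param samples output of [genotype_samples()].
#' @param masses mass table with `mass_id`, `mother_id`, `group_id`, `week`.
#' @param events mating events.
#' @param roster roster with `is_focal`.
#' @return data frame `group_id`, `mother_id`, `week`, `x`, `k`, `n`.
#' @export
paternity_observations <- function(samples, masses, events, roster) {
  focal_of <- stats::setNames(roster$snail_id[roster$is_focal],
                              roster$group_id[roster$is_focal])
  m <- merge(samples, masses[, c("mass_id", "mother_id", "group_id", "week")],
             by = "mass_id")
  m <- m[m$mother_id != focal_of[m$group_id], , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(group_id = character(), mother_id = character(),
                      week = integer(), x = numeric(), k = integer(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(m$mother_id, m$week, sep = "|")
  out <- list()
  for (kk in unique(key)) {
    sub <- m[key == kk, , drop = FALSE]
    foc <- focal_of[[sub$group_id[1]]]
    out[[length(out) + 1L]] <- data.frame(
      group_id = sub$group_id[1], mother_id = sub$mother_id[1],
      week = sub$week[1],
      x = female_mating_share(events, sub$mother_id[1], foc, sub$week[1]),
      k = sum(sub$n_focal), n = sum(sub$n_focal + sub$n_nonfocal),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out[out$n > 0, , drop = FALSE]
}

#' Fit the paternity-share regression
#'
#' Logistic regression of focal-fathered egg counts (`k` out of `n`) on the
#' focal's share of the mother's female matings, with the number of assignable
#' genotyped eggs as binomial weight. Standard errors are corrected for
#' overdispersion by the Pearson-based dispersion estimate
#' `phi = Pearson chi-square / (N - 2)` (quasi-likelihood scaling); the
#' likelihood-ratio statistic against the intercept-only binomial model is
#' stored as the fit statistic.
#'
#' @param obs data frame with columns `x`, `k`, `n` (see
#'   [paternity_observations()]).
#' @return an object of class `"paternity_glm"`: coefficients on the log-odds
#'   scale, scaled standard errors, `dispersion`, `lr_stat` (1 df), and
#'   `n_obs`. Complete separation (all `k = 0` or all `k = n`) is flagged with
#'   `separation = TRUE` and a clamped intercept-only fit.
#' @export
fit_paternity_glm <- function(obs) {
  if (nrow(obs) < 2 || length(unique(obs$x)) < 2) {
    stop("paternity regression needs >= 2 observations with distinct x")
  }
  if (sum(obs$n) == 0) stop("no assignable genotyped eggs")
  if (all(obs$k == 0) || all(obs$k == obs$n)) {
    rate <- min(max(sum(obs$k) / sum(obs$n), 1e-6), 1 - 1e-6)
    return(structure(list(coefficients = c(intercept = stats::qlogis(rate),
                                           slope = 0),
                          se = c(intercept = NA_real_, slope = NA_real_),
                          dispersion = NA_real_, lr_stat = 0, lr_df = 1L,
                          n_obs = nrow(obs), separation = TRUE),
                     class = "paternity_glm"))
  }
  fit <- stats::glm(cbind(k, n - k) ~ x, family = stats::quasibinomial(),
                    data = obs)
  sm <- summary(fit)
  phi <- sm$dispersion  # Pearson chi-square / (N - 2)
  # LR statistic on the binomial (phi = 1) scale, as reported by the fit
  binfit <- stats::glm(cbind(k, n - k) ~ x, family = stats::binomial(),
                       data = obs)
  lr <- binfit$null.deviance - binfit$deviance
  structure(list(coefficients = c(intercept = unname(stats::coef(fit)[1]),
                                  slope = unname(stats::coef(fit)[2])),
                 se = c(intercept = sm$coefficients[1, 2],
                        slope = sm$coefficients[2, 2]),
                 dispersion = phi, lr_stat = lr, lr_df = 1L,
                 n_obs = nrow(obs), separation = FALSE),
            class = "paternity_glm")
}

#' @export
print.paternity_glm <- function(x, ...) {
  cat("Paternity-share logistic regression (overdispersion-corrected)\n")
  cat(sprintf("  logit(share) = %.3f + %.3f * mating share  (n = %d)\n",
              x$coefficients[1], x$coefficients[2], x$n_obs))
  if (isTRUE(x$separation)) {
    cat("  complete separation: clamped intercept-only fit\n")
  } else {
    cat(sprintf("  scaled SE: %.3f / %.3f; dispersion phi = %.2f; LR chi-sq(1) = %.2f\n",
                x$se[1], x$se[2], x$dispersion, x$lr_stat))
  }
  invisible(x)
}

#' @export
coef.paternity_glm <- function(object, ...) object$coefficients

#' Predicted paternity share
#'
#' Inverse-logit of the fitted linear predictor at a mating share `x`.
#'
#' @param object a `"paternity_glm"`.
#' @param x mating share(s) in `[0, 1]`.
#' @param ... unused.
#' @return predicted share(s) in `(0, 1)`.
#' @export
predict.paternity_glm <- function(object, x, ...) {
  if (is.null(object$coefficients)) stop("unfitted paternity model")
  if (any(x < 0 | x > 1)) stop("mating share must lie in [0, 1]")
  stats::plogis(object$coefficients[["intercept"]] +
                  object$coefficients[["slope"]] * x)
}

#' @rdname predict.paternity_glm
#' @param model a `"paternity_glm"`.
#' @export
predict_paternity_share <- function(model, x) predict(model, x)

#' Estimated male reproductive success of a focal
#'
#' Sums the focal's estimated contribution over all egg masses laid by its
#' group partners through the given cumulative week: genotyped masses
#' contribute their observed focal fraction `n_focal / (n_focal + n_nonfocal)`
#' times the mass's egg count; non-genotyped masses contribute the regression
#' prediction at the focal's share of the mother's female matings (cumulated
#' through the week the mass was laid) times the egg count. Predicted shares
#' are not renormalized across candidate fathers.
#'
#' @param masses mass table with `egg_count` filled.
#' @param samples output of [genotype_samples()] (may be `NULL` when all
#'   masses are ungenotyped).
#' @param model a `"paternity_glm"`, required when non-genotyped masses exist.
#' @param events mating events.
#' @param roster roster table.
#' @param focal_id the focal snail.
#' @param week cumulative week.
#' @return estimated eggs fathered (non-negative real).
#' @export
male_reproductive_success <- function(masses, samples, model, events, roster,
                                      focal_id, week) {
  gid <- roster$group_id[roster$snail_id == focal_id]
  partners <- roster$snail_id[roster$group_id == gid &
                                roster$snail_id != focal_id]
  mm <- masses[masses$mother_id %in% partners & masses$week <= week, ,
               drop = FALSE]
  if (!nrow(mm)) return(0)
  obs_share <- rep(NA_real_, nrow(mm))
  if (!is.null(samples) && nrow(samples)) {
    idx <- match(mm$mass_id, samples$mass_id)
    hit <- !is.na(idx)
    n_ass <- samples$n_focal[idx[hit]] + samples$n_nonfocal[idx[hit]]
    share <- ifelse(n_ass > 0, samples$n_focal[idx[hit]] / n_ass, NA_real_)
    if (anyNA(share)) {
      warning("genotyped mass with no assignable eggs: using model prediction")
    }
    obs_share[hit] <- share
  }
  need_model <- is.na(obs_share)
  if (any(need_model) && is.null(model)) {
    stop("non-genotyped masses present but no paternity model supplied")
  }
  if (any(need_model)) {
    x <- vapply(which(need_model), function(i) {
      female_mating_share(events, mm$mother_id[i], focal_id, mm$week[i])
    }, numeric(1))
    obs_share[need_model] <- predict(model, x)
  }
  sum(obs_share * mm$egg_count)
}
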