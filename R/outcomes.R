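# Offspring outcomes: 14-day developmental tallies (undeveloped, early
# embryo, late embryo, hatched) compared across partner-availability
# treatments with a Pearson chi-square test and pairwise rank-sum tests.

DEV_CATEGORIES <- c("undeveloped", "early", "late", "hatched")

#' Tally developmental outcomes per treatment
#'
#' Aggregates per-mass category counts into per-treatment totals and per-mass
#' proportions. Masses with zero eggs are excluded with a warning.
#'
#' @param development data frame with `mass_id`, `treatment`,
#'   `n_undeveloped`, `n_early`, `n_late`, `n_hatched`.
#' @return list with `totals` (treatment x category count matrix) and
#'   `proportions` (per-mass data frame with category proportions).
#' @export
tally_development <- function(development) {
  cnt <- as.matrix(development[, paste0("n_", DEV_CATEGORIES)])
  tot <- rowSums(cnt)
  if (any(tot == 0)) {
    warning(sprintf("excluding %d zero-egg mass(es)", sum(tot == 0)))
    development <- development[tot > 0, , drop = FALSE]
    cnt <- cnt[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  totals <- rowsum(cnt, development$treatment)
  colnames(totals) <- DEV_CATEGORIES
  prop <- sweep(cnt, 1, tot, "/")
  colnames(prop) <- DEV_CATEGORIES
  proportions <- cbind(development[, c("mass_id", "treatment")],
                       as.data.frame(prop), n_eggs = tot)
  rownames(proportions) <- NULL
  list(totals = totals, proportions = proportions)
}

#' Chi-square test of developmental outcomes across treatments
#'
#' Pearson chi-square test on the treatment-by-category contingency table of
#' egg counts, with `df = (rows - 1)(cols - 1)`.
#'
#' @param totals treatment-by-category count matrix (from
#'   [tally_development()]).
#' @return named vector `chisq`, `df`, `p`.
#' @export
chi_square_outcomes <- function(totals) {
  totals <- as.matrix(totals)
  totals <- totals[, colSums(totals) > 0, drop = FALSE]
  totals <- totals[rowSums(totals) > 0, , drop = FALSE]
  if (nrow(totals) < 2 || ncol(totals) < 2) {
    stop("need >= 2 treatments and >= 2 categories with non-zero totals")
  }
  expected <- outer(rowSums(totals), colSums(totals)) / sum(totals)
  if (any(expected == 0)) {
    stop("zero expected count: pool sparse categories before testing")
  }
  ht <- stats::chisq.test(totals, correct = FALSE)
  c(chisq = unname(ht$statistic), df = unname(ht$parameter),
    p = unname(ht$p.value))
}

#' Pairwise Wilcoxon rank-sum comparison of per-mass proportions
#'
#' Rank-sum test of one developmental category's per-mass proportions between
#' two treatments, using the normal approximation with tie and continuity
#' corrections (the convention of standard statistical software) and reporting
#' the standardized statistic Z (sign follows the first group's rank sum) and
#' its two-sided p-value. Per-mass proportions are the unit of analysis
#' because treatment-level replication is small.
#'
#' @param prop1,prop2 per-mass proportions of the category in the two
#'   treatments.
#' @return named vector `Z`, `p`.
#' @export
pairwise_wilcoxon <- function(prop1, prop2) {
  n1 <- length(prop1); n2 <- length(prop2)
  if (n1 < 1 || n2 < 1) stop("each treatment needs at least one egg mass")
  all_v <- c(prop1, prop2)
  r <- rank(all_v)
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(c(Z = 0, p = 1))  # everything tied
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  c(Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare one developmental category between all treatment pairs
#'
#' Runs [pairwise_wilcoxon()] on per-mass proportions for every pair of
#' treatments, without multiplicity adjustment.
#'
#' @param proportions per-mass proportions from [tally_development()].
#' @param category one of `"undeveloped"`, `"early"`, `"late"`, `"hatched"`.
#' @return data frame `treatment1`, `treatment2`, `Z`, `p`.
#' @export
pairwise_outcome_tests <- function(proportions, category = "hatched") {
  if (!category %in% DEV_CATEGORIES) stop("unknown category")
  trts <- sort(unique(proportions$treatment))
  out <- list()
  for (i in seq_along(trts)) {
    for (j in seq_along(trts)) {
      if (j <= i) next
      v1 <- proportions[[category]][proportions$treatment == trts[i]]
      v2 <- proportions[[category]][proportions$treatment == trts[j]]
      w <- pairwise_wilcoxon(v1, v2)
      out[[length(out) + 1L]] <- data.frame(
        treatment1 = trts[i], treatment2 = trts[j], category = category,
        Z = w[["Z"]], p = w[["p"]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
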