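# Tabulation: raw event/mass tables -> per-focal cumulative weekly success
# records, with egg-count calibration from egg-mass length and death censoring.

#' Cumulative mating success through a week
#'
#' Counts, for each requested snail, the copulations performed in the male role
#' (as sperm donor, `MS_m`) and the female role (as recipient, `MS_f`) in all
#' events up to and including `week`. Mating success is the cumulative number
#' of matings, not of distinct mates. Every event increments exactly one
#' snail's `MS_m` and one snail's `MS_f`.
#'
#' @param events data frame with columns `week`, `donor_id`, `recipient_id`.
#' @param focal_ids snails to report; absent snails get zero counts.
#' @param week cumulative week (events with `week <=` this are counted).
#' @return data frame `focal_id`, `MS_m`, `MS_f`.
#' @export
cumulative_mating_success <- function(events, focal_ids, week) {
  keep <- events$week <= week
  tm <- table(factor(events$donor_id[keep], levels = focal_ids))
  tf <- table(factor(events$recipient_id[keep], levels = focal_ids))
  data.frame(focal_id = focal_ids, MS_m = as.integer(tm), MS_f = as.integer(tf),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit an egg-count calibration line for one stratum
#'
#' Ordinary least-squares regression of directly counted egg numbers on
#' egg-mass length, used to estimate the egg count of uncounted masses of the
#' same stratum (treatment by week in the emulated design, where 24 random
#' masses per treatment are counted each week).
#'
#' @param lengths_mm lengths of the counted masses (mm).
#' @param counts their directly counted egg numbers.
#' @param stratum optional label stored on the model.
#' @return an object of class `"egg_calibration"`: list with `intercept`,
#'   `slope`, `n`, `residual_sd`, `stratum`. If all lengths are identical the
#'   fit is degenerate: slope 0 and intercept at the mean count, flagged with
#'   `degenerate = TRUE`.
#' @export
fit_egg_count_calibration <- function(lengths_mm, counts, stratum = NULL) {
  if (length(lengths_mm) < 2 || length(lengths_mm) != length(counts)) {
    stop("calibration needs >= 2 counted masses with matching lengths")
  }
  if (stats::var(lengths_mm) == 0) {
    return(structure(list(intercept = mean(counts), slope = 0,
                          n = length(counts),
                          residual_sd = stats::sd(counts),
                          stratum = stratum, degenerate = TRUE),
                     class = "egg_calibration"))
  }
  slope <- stats::cov(lengths_mm, counts) / stats::var(lengths_mm)
  intercept <- mean(counts) - slope * mean(lengths_mm)
  res <- counts - intercept - slope * lengths_mm
  rsd <- if (length(counts) > 2) sqrt(sum(res^2) / (length(counts) - 2)) else 0
  structure(list(intercept = intercept, slope = slope, n = length(counts),
                 residual_sd = rsd, stratum = stratum, degenerate = FALSE),
            class = "egg_calibration")
}

#' @export
print.egg_calibration <- function(x, ...) {
  cat(sprintf("Egg-count calibration%s: eggs = %.2f + %.2f * length_mm (n = %d%s)\n",
              if (is.null(x$stratum)) "" else paste0(" [", x$stratum, "]"),
              x$intercept, x$slope, x$n,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

# Fit calibrations per treatment-week stratum with fallbacks: stratum ->
# treatment-pooled -> global, whenever fewer than 2 counted masses exist.
fit_calibration_set <- function(masses) {
  cm <- masses[masses$counted, , drop = FALSE]
  if (!nrow(cm)) stop("no counted masses: cannot calibrate egg counts")
  global <- fit_egg_count_calibration(cm$length_mm, cm$counted_eggs, "global")
  set <- list(global = global)
  for (trt in unique(masses$treatment)) {
    ct <- cm[cm$treatment == trt, , drop = FALSE]
    trt_model <- if (nrow(ct) >= 2) {
      fit_egg_count_calibration(ct$length_mm, ct$counted_eggs, trt)
    } else global
    set[[trt]] <- trt_model
    for (w in unique(masses$week[masses$treatment == trt])) {
      cw <- ct[ct$week == w, , drop = FALSE]
      key <- paste(trt, w, sep = ".")
      set[[key]] <- if (nrow(cw) >= 2) {
        fit_egg_count_calibration(cw$length_mm, cw$counted_eggs, key)
      } else trt_model
    }
  }
  set
}

#' Fill in egg counts for all masses
#'
#' Directly counted masses keep their count; the rest get the calibrated
#' estimate `max(0, round(intercept + slope * length))` from their
#' treatment-by-week stratum model (falling back to treatment-pooled, then
#' global, where a stratum had fewer than two counted masses).
#'
#' @param masses data frame with `treatment`, `week`, `length_mm`, `counted`,
#'   `counted_eggs`.
#' @param calibration optional precomputed list from `fit_calibration_set`;
#'   fitted from `masses` if `NULL`.
#' @return `masses` with an `egg_count` column filled for every row.
#' @export
estimate_egg_counts <- function(masses, calibration = NULL) {
  if (is.null(calibration)) calibration <- fit_calibration_set(masses)
  key <- paste(masses$treatment, masses$week, sep = ".")
  egg <- numeric(nrow(masses))
  for (i in seq_len(nrow(masses))) {
    if (masses$counted[i]) {
      egg[i] <- masses$counted_eggs[i]
    } else {
      m <- calibration[[key[i]]]
      if (is.null(m)) m <- calibration[[masses$treatment[i]]]
      if (is.null(m)) m <- calibration$global
      if (is.null(m)) stop(sprintf("no calibration model for stratum %s", key[i]))
      egg[i] <- max(0, round(m$intercept + m$slope * masses$length_mm[i]))
    }
  }
  masses$egg_count <- egg
  masses
}

#' Cumulative female reproductive success
#'
#' Eggs laid by each mother in all masses through the given week (egg counts
#' must already be filled in, directly or by calibration).
#'
#' @param masses data frame with `mother_id`, `week`, `egg_count`.
#' @param mother_ids snails to report (zero for mothers without masses).
#' @param week cumulative week.
#' @return data frame `focal_id`, `RS_f`.
#' @export
female_reproductive_success <- function(masses, mother_ids, week) {
  keep <- masses$week <= week
  agg <- tapply(masses$egg_count[keep], masses$mother_id[keep], sum)
  rs <- stats::setNames(rep(0, length(mother_ids)), mother_ids)
  hit <- intersect(names(agg), mother_ids)
  rs[hit] <- agg[hit]
  data.frame(focal_id = mother_ids, RS_f = as.numeric(rs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Censor success records at death
#'
#' Focals that died are excluded from their death week onwards: records of a
#' focal at weeks greater than or equal to its death week are removed; earlier
#' weeks are retained. Partners' deaths do not remove a focal's records.
#'
#' @param records data frame with `focal_id` and `week`.
#' @param deaths data frame with `snail_id` and `week` of death.
#' @param weeks total number of weeks in the experiment (for validation).
#' @return the censored records.
#' @export
apply_censoring <- function(records, deaths, weeks) {
  if (!nrow(deaths)) return(records)
  if (any(deaths$week < 1 | deaths$week > weeks)) {
    stop("death week outside 1..weeks")
  }
  dw <- stats::setNames(deaths$week, deaths$snail_id)
  lim <- dw[records$focal_id]
  keep <- is.na(lim) | records$week < lim
  records[keep, , drop = FALSE]
}

#' Build per-focal cumulative weekly success records
#'
#' The central tabulation: for each focal of the multiple-partner treatment and
#' each cumulative week, the cumulative male and female mating success, the
#' calibrated cumulative egg output (`RS_f`), and — when a paternity model can
#' be fitted — the estimated cumulative male reproductive success (`RS_m`).
#' Records after a focal's death are censored.
#'
#' @param xp a `"snail_experiment"`, or a list with the same table layout
#'   (`roster`, `events`, `masses`, `genotypes`, `deaths`, `config`).
#' @param weeks weeks to tabulate (default all).
#' @param paternity if `TRUE` (default) estimate `RS_m` via the paternity
#'   module; otherwise `RS_m` is `NA`.
#' @return data frame `focal_id`, `week`, `MS_m`, `MS_f`, `RS_f`, `RS_m`,
#'   `alive`.
#' @export
build_success_records <- function(xp, weeks = NULL,
                                  paternity = TRUE) {
  cfg <- xp$config
  if (is.null(weeks)) weeks <- seq_len(cfg$weeks)
  roster <- xp$roster
  focals <- roster$snail_id[roster$is_focal & roster$treatment == "multiple"]
  masses <- estimate_egg_counts(xp$masses)
  pat_fit <- NULL
  samples <- NULL
  if (paternity && nrow(xp$genotypes)) {
    samples <- genotype_samples(xp$genotypes, masses, roster)
    obs <- paternity_observations(samples, masses, xp$events, roster)
    pat_fit <- if (nrow(obs) >= 2 && length(unique(obs$x)) >= 2) {
      fit_paternity_glm(obs)
    } else NULL
  }
  rows <- list()
  for (w in weeks) {
    ms <- cumulative_mating_success(xp$events, focals, w)
    rf <- female_reproductive_success(masses, focals, w)
    rec <- merge(ms, rf, by = "focal_id")
    rec$week <- w
    if (paternity && !is.null(samples)) {
      rec$RS_m <- vapply(rec$focal_id, function(f) {
        male_reproductive_success(masses, samples, pat_fit, xp$events,
                                  roster, f, w)
      }, numeric(1), USE.NAMES = FALSE)
    } else {
      rec$RS_m <- NA_real_
    }
    rows[[length(rows) + 1L]] <- rec
  }
  out <- do.call(rbind, rows)
  dw <- stats::setNames(xp$deaths$week, xp$deaths$snail_id)
  lim <- dw[out$focal_id]
  out$alive <- is.na(lim) | out$week < lim
  out <- apply_censoring(out, xp$deaths, cfg$weeks)
  out <- out[order(out$week, out$focal_id),
             c("focal_id", "week", "MS_m", "MS_f", "RS_f", "RS_m", "alive")]
  rownames(out) <- NULL
  out
}
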