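# Synthetic mating-system generator: group-housed simultaneous hermaphrodites
# with unilateral copulation, allosperm storage and multinomial fertilization.
# Every downstream stage of the package can be exercised against the ground
# truth this generator records.

ALLELES <- c("A", "B", "C")
FOCAL_ALLELE <- "C"   # private to focals, so their paternity is unambiguous
SELF_ID <- "SELF"

# Zero-row templates, built once (constructing them per call is measurable in
# replicate studies).
EMPTY_EVENTS <- data.frame(week = integer(), trial = integer(),
                           initiator_id = character(),
                           donor_id = character(),
                           recipient_id = character(),
                           stringsAsFactors = FALSE)
EMPTY_MASSES <- local({
  d <- data.frame(mother_id = character(), week = integer(),
                  true_egg_count = integer(), raw_length = numeric(),
                  stringsAsFactors = FALSE)
  d$paternity <- list()
  d
})

# Days within a week on which mating trials take place (two 7-h trials on
# days 1 and 4 in the emulated design).
trial_days <- function(trials_per_week) {
  if (trials_per_week == 2L) return(c(1L, 4L))
  as.integer(round(seq(1, 6, length.out = trials_per_week)))
}

#' Simulate one mating trial of a group
#'
#' Each living snail initiates a Poisson-distributed number of copulations; the
#' partner is chosen uniformly among the other living group members, and the
#' initiator takes the male (sperm-donor) role with probability `role_bias`.
#' Matings are unilateral: no reciprocal return mating is forced.
#'
#' @param snail_ids identifiers of the living snails in the group.
#' @param week,trial indices recorded on the events.
#' @param mating_rate mean copulations initiated per snail.
#' @param role_bias probability the initiator acts as sperm donor.
#' @return data frame of mating events (possibly zero rows): `week`, `trial`,
#'   `initiator_id`, `donor_id`, `recipient_id`. Draws from the current RNG
#'   stream.
#' @export
simulate_mating_trial <- function(snail_ids, week, trial, mating_rate,
                                  role_bias = 0.5) {
  n <- length(snail_ids)
  if (n < 2) return(EMPTY_EVENTS)
  n_init <- stats::rpois(n, mating_rate)
  total <- sum(n_init)
  if (total == 0) return(EMPTY_EVENTS)
  initiator <- rep(snail_ids, n_init)
  partner <- vapply(initiator, function(s) {
    others <- snail_ids[snail_ids != s]
    others[sample.int(length(others), 1L)]
  }, character(1), USE.NAMES = FALSE)
  as_male <- stats::runif(total) < role_bias
  fast_df(list(week = rep(as.integer(week), total),
               trial = rep(as.integer(trial), total),
               initiator_id = initiator,
               donor_id = ifelse(as_male, initiator, partner),
               recipient_id = ifelse(as_male, partner, initiator)))
}

#' Create an empty allosperm store
#'
#' @return a sperm store: a list with parallel vectors `donor`, `deposit_day`
#'   and `amount` (one element per deposit) and `day`, the day to which the
#'   store has been advanced.
#' @export
new_sperm_store <- function() {
  list(donor = character(0), deposit_day = numeric(0), amount = numeric(0),
       day = 0)
}

#' Advance an allosperm store in time and add received donations
#'
#' Stored amounts decay by a constant factor per day and deposits older than
#' the retention limit are discarded (the emulated species retains received
#' sperm for about 62 days). Each donation received adds one unit from its
#' donor, deposited on `day`.
#'
#' @param store a sperm store from [new_sperm_store()] or a previous update.
#' @param donors character vector of donor identifiers received on `day`
#'   (one element per copulation; may be empty).
#' @param day current day; must not precede the store's day.
#' @param decay per-day retention fraction in (0, 1].
#' @param retention_days age in days beyond which a deposit is removed.
#' @return the updated store.
#' @export
update_sperm_store <- function(store, donors, day, decay = 1,
                               retention_days = 62) {
  elapsed <- day - store$day
  if (elapsed < 0) stop("negative day increment in sperm store update")
  donor <- store$donor
  dep_day <- store$deposit_day
  amount <- store$amount
  if (length(amount)) {
    amount <- amount * decay^elapsed
    keep <- day - dep_day <= retention_days
    donor <- donor[keep]; dep_day <- dep_day[keep]; amount <- amount[keep]
  }
  k <- length(donors)
  if (k) {
    donor <- c(donor, donors)
    dep_day <- c(dep_day, rep(day, k))
    amount <- c(amount, rep(1, k))
  }
  list(donor = donor, deposit_day = dep_day, amount = amount, day = day)
}

# Total stored amount per donor, as a named vector.
store_shares <- function(store) {
  if (!length(store$amount)) return(numeric(0))
  tapply(store$amount, store$donor, sum)
}

#' Simulate one week's egg laying for a snail
#'
#' The weekly egg total is negative-binomial with mean `fecundity_mean`, split
#' over a uniformly drawn number of masses. Each egg's father is drawn
#' multinomially with odds proportional to the donor's stored sperm raised to
#' `paternity_exponent`; with an empty store and selfing allowed, all eggs are
#' self-fertilized. At the boundary `paternity_exponent = 0` (the
#' random-paternity calibration null, reading `0^0 = 1`) an inseminated
#' mother's eggs take a father uniformly among her living group partners,
#' independent of who donated how often; a never-inseminated mother still
#' selfs. Raw (pre-calibration) mass lengths are generated from the linear
#' length-count relation plus Gaussian noise.
#'
#' @param mother_id the laying snail.
#' @param store its current allosperm store (already advanced to laying day).
#' @param week week index recorded on the masses.
#' @param cfg a [simulation_config()].
#' @param partners identifiers of the mother's living group partners, used
#'   only in the `paternity_exponent = 0` regime.
#' @return data frame with one row per egg mass: `mother_id`, `week`,
#'   `true_egg_count`, `raw_length`, plus a list column `paternity` of named
#'   father -> egg-count vectors. Zero rows if no eggs are laid.
#' @export
simulate_oviposition <- function(mother_id, store, week, cfg,
                                 partners = character(0)) {
  shares <- store_shares(store)
  shares <- shares[shares > 0]
  if (cfg$paternity_exponent == 0 && length(shares) && length(partners)) {
    # random-paternity null: any living partner may sire, uniformly
    shares <- stats::setNames(rep(1, length(partners)), partners)
  }
  if (!length(shares) && !cfg$selfing_allowed) return(EMPTY_MASSES)
  total <- stats::rnbinom(1, mu = cfg$fecundity_mean,
                          size = cfg$fecundity_dispersion)
  if (total == 0) return(EMPTY_MASSES)
  rng <- cfg$masses_per_week_range
  n_masses <- sample1(seq(rng[1], rng[2]))
  n_masses <- min(n_masses, total)
  split <- as.integer(stats::rmultinom(1, total, rep(1, n_masses)))
  split <- split[split > 0]
  n_masses <- length(split)
  pat <- vector("list", n_masses)
  for (i in seq_len(n_masses)) {
    if (length(shares)) {
      probs <- shares^cfg$paternity_exponent
      counts <- as.integer(stats::rmultinom(1, split[i], probs))
      names(counts) <- names(shares)
      pat[[i]] <- counts[counts > 0]
    } else {
      pat[[i]] <- stats::setNames(split[i], SELF_ID)
    }
  }
  raw_len <- cfg$calibration_intercept + cfg$calibration_slope * split +
    stats::rnorm(n_masses, 0, cfg$length_noise_sd)
  out <- fast_df(list(mother_id = rep(mother_id, n_masses),
                      week = rep(as.integer(week), n_masses),
                      true_egg_count = split, raw_length = raw_len))
  out$paternity <- pat
  out
}

# Simulate one group for the whole experiment under the current RNG stream.
# Returns events, deaths, masses (with list-column paternity), and genotypes.
simulate_group <- function(roster_g, cfg) {
  ids <- roster_g$snail_id
  genotype <- stats::setNames(
    lapply(seq_len(nrow(roster_g)), function(i)
      c(roster_g$allele1[i], roster_g$allele2[i])), ids)
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  death_week <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  stores <- stats::setNames(lapply(ids, function(i) new_sperm_store()), ids)
  tdays <- trial_days(cfg$trials_per_week)
  is_multi <- roster_g$treatment[1] == "multiple"
  events <- list(); masses <- list()

  for (w in seq_len(cfg$weeks)) {
    # mortality at the start of the week: the dying snail contributes nothing
    # from this week onwards
    for (s in ids[alive]) {
      if (stats::runif(1) < cfg$weekly_death_prob) {
        alive[s] <- FALSE
        death_week[s] <- w
      }
    }
    live <- ids[alive]
    for (t in seq_len(cfg$trials_per_week)) {
      day <- (w - 1L) * 7L + tdays[t]
      ev <- simulate_mating_trial(live, w, t, cfg$mating_rate, cfg$role_bias)
      if (nrow(ev)) {
        events[[length(events) + 1L]] <- ev
        for (s in unique(ev$recipient_id)) {
          stores[[s]] <- update_sperm_store(
            stores[[s]], ev$donor_id[ev$recipient_id == s], day,
            cfg$sperm_decay, cfg$sperm_retention_days)
        }
      }
    }
    lay_day <- w * 7L
    for (s in live) {
      stores[[s]] <- update_sperm_store(stores[[s]], character(0), lay_day,
                                        cfg$sperm_decay,
                                        cfg$sperm_retention_days)
      mm <- simulate_oviposition(s, stores[[s]], w, cfg,
                                 partners = setdiff(live, s))
      if (nrow(mm)) {
        mm$followed <- FALSE
        if (is_multi && w %in% cfg$followed_weeks) {
          mm$followed[sample.int(nrow(mm), 1L)] <- TRUE
        }
        masses[[length(masses) + 1L]] <- mm
      }
    }
  }

  events <- if (length(events)) do.call(rbind, events) else EMPTY_EVENTS
  masses <- if (length(masses)) do.call(rbind, masses) else NULL

  # offspring genotypes for followed masses: sample eggs without replacement
  # from the true father composition, then draw one maternal and one paternal
  # allele per egg
  genotypes <- list()
  if (!is.null(masses)) {
    grange <- cfg$genotyped_per_mass_range
    for (i in which(masses$followed)) {
      pat <- masses$paternity[[i]]
      fathers <- rep(names(pat), pat)
      n_g <- min(sample1(seq(grange[1], grange[2])), length(fathers))
      picked <- sample(fathers, n_g)
      mo <- genotype[[masses$mother_id[i]]]
      a_mat <- mo[sample.int(2L, n_g, replace = TRUE)]
      a_pat <- vapply(picked, function(f) {
        fg <- if (f == SELF_ID) mo else genotype[[f]]
        fg[sample.int(2L, 1L)]
      }, character(1), USE.NAMES = FALSE)
      genotypes[[length(genotypes) + 1L]] <-
        fast_df(list(row = rep(i, n_g), egg_index = seq_len(n_g),
                     allele1 = a_mat, allele2 = a_pat))
    }
  }
  list(events = events, masses = masses, genotypes = genotypes,
       death_week = death_week)
}

#' Simulate a full mating experiment
#'
#' Generates a complete synthetic experiment under the emulated three-treatment
#' design (multiple partners, single partner, no partner), with per-group
#' random-number substreams derived from the root seed. The result records the
#' full ground-truth paternity of every egg mass, so recovery of male
#' reproductive success by the estimation pipeline can be checked exactly.
#'
#' @param cfg a [simulation_config()].
#' @return an object of class `"snail_experiment"`: a list with data frames
#'   `roster`, `events`, `masses`, `paternity` (mass, father, eggs),
#'   `genotypes`, `development` (14-day outcome tallies of end-of-experiment
#'   masses), `deaths`, and the `config` used.
#' @examples
#' cfg <- simulation_config(n_groups_multi = 2, n_pairs_single = 1,
#'                          n_isolated = 1, weeks = 2, seed = 42)
#' xp <- simulate_experiment(cfg)
#' head(xp$events)
#' @export
simulate_experiment <- function(cfg) {
  validate_config(cfg)
  roster <- build_roster(cfg)
  groups <- split(roster, roster$group_id)
  ev_all <- list(); mass_all <- list(); gen_all <- list()
  roster$death_week <- NA_integer_
  for (gid in names(groups)) {
    res <- with_substream(substream_seed(cfg$seed, gid), {
      simulate_group(groups[[gid]], cfg)
    })
    if (nrow(res$events)) {
      res$events$group_id <- gid
      ev_all[[gid]] <- res$events
    }
    if (!is.null(res$masses)) {
      res$masses$group_id <- gid
      res$masses$treatment <- groups[[gid]]$treatment[1]
      mass_all[[gid]] <- res$masses
      gen_all[[gid]] <- res$genotypes
    }
    roster$death_week[match(names(res$death_week), roster$snail_id)] <-
      res$death_week
  }

  events <- if (length(ev_all)) do.call(rbind, ev_all) else
    data.frame(group_id = character(), week = integer(), trial = integer(),
               initiator_id = character(), donor_id = character(),
               recipient_id = character(), stringsAsFactors = FALSE)
  rownames(events) <- NULL
  if (nrow(events)) {
    events <- events[, c("group_id", "week", "trial", "initiator_id",
                         "donor_id", "recipient_id")]
    events <- cbind(event_id = sprintf("E%05d", seq_len(nrow(events))), events,
                    stringsAsFactors = FALSE)
  } else {
    events <- cbind(event_id = character(0), events)
  }

  masses <- if (length(mass_all)) do.call(rbind, mass_all) else NULL
  genotypes <- data.frame(mass_id = character(), egg_index = integer(),
                          allele1 = character(), allele2 = character(),
                          stringsAsFactors = FALSE)
  paternity <- data.frame(mass_id = character(), father_id = character(),
                          n_eggs = integer(), stringsAsFactors = FALSE)
  development <- data.frame(mass_id = character(), treatment = character(),
                            n_undeveloped = integer(), n_early = integer(),
                            n_late = integer(), n_hatched = integer(),
                            stringsAsFactors = FALSE)
  if (!is.null(masses)) {
    rownames(masses) <- NULL
    masses$mass_id <- sprintf("EM%05d", seq_len(nrow(masses)))
    # recorded lengths: within each treatment-week stratum, rank-match the
    # noisy lengths to the egg counts so length is monotone in count by
    # construction, then record to the nearest 0.5 mm
    masses$length_mm <- masses$raw_length
    for (str in split(seq_len(nrow(masses)),
                      list(masses$treatment, masses$week), drop = TRUE)) {
      lens <- sort(masses$raw_length[str])
      ord <- rank(masses$true_egg_count[str], ties.method = "first")
      masses$length_mm[str] <- lens[ord]
    }
    masses$length_mm <- pmax(round_half_mm(masses$length_mm), 0.5)

    # direct egg counts for the calibration subsample
    masses$counted <- FALSE
    with_substream(substream_seed(cfg$seed, "counted"), {
      for (str in split(seq_len(nrow(masses)),
                        list(masses$treatment, masses$week), drop = TRUE)) {
        take <- min(cfg$counted_per_stratum, length(str))
        if (take > 0) masses$counted[sample(str, take)] <- TRUE
      }
    })
    masses$counted_eggs <- ifelse(masses$counted, masses$true_egg_count,
                                  NA_integer_)

    paternity <- do.call(rbind, lapply(seq_len(nrow(masses)), function(i) {
      p <- masses$paternity[[i]]
      data.frame(mass_id = masses$mass_id[i], father_id = names(p),
                 n_eggs = as.integer(p), stringsAsFactors = FALSE)
    }))
    rownames(paternity) <- NULL

    # genotype blocks carry group-local mass row indices; resolve them to mass
    # ids via per-group row offsets in the combined table
    offsets <- cumsum(c(0, vapply(mass_all, nrow, integer(1))))
    names(offsets) <- c(names(mass_all), ".end")
    blocks <- list()
    for (gid in names(mass_all)) {
      for (g in gen_all[[gid]]) {
        g$mass_id <- masses$mass_id[offsets[[gid]] + g$row]
        blocks[[length(blocks) + 1L]] <- g
      }
    }
    if (length(blocks)) {
      genotypes <- do.call(rbind, blocks)[, c("mass_id", "egg_index",
                                              "allele1", "allele2")]
      rownames(genotypes) <- NULL
    }

    development <- simulate_development(masses, cfg)
    masses <- masses[, c("mass_id", "mother_id", "group_id", "treatment",
                         "week", "length_mm", "true_egg_count", "counted",
                         "counted_eggs", "followed")]
  }

  deaths <- roster[!is.na(roster$death_week), c("snail_id", "death_week")]
  names(deaths) <- c("snail_id", "week")
  rownames(deaths) <- NULL

  structure(list(roster = roster, events = events, masses = masses,
                 paternity = paternity, genotypes = genotypes,
                 development = development, deaths = deaths, config = cfg),
            class = "snail_experiment")
}

# 14-day developmental outcomes for end-of-experiment masses: one final-week
# mass per focal mother, category probabilities by treatment.
simulate_development <- function(masses, cfg) {
  trt_idx <- c(multiple = 1L, single = 2L, none = 3L)
  out <- list()
  with_substream(substream_seed(cfg$seed, "development"), {
    final <- masses[masses$week == max(masses$week), , drop = FALSE]
    for (trt in unique(final$treatment)) {
      sub <- final[final$treatment == trt, , drop = FALSE]
      pick <- unlist(lapply(split(seq_len(nrow(sub)), sub$mother_id),
                            function(ix) ix[sample.int(length(ix), 1L)]))
      h <- cfg$hatch_prob[[trt_idx[[trt]]]]
      u <- cfg$undeveloped_prob[[trt_idx[[trt]]]]
      rest <- 1 - h - u
      probs <- c(u, 0.55 * rest, 0.45 * rest, h)
      for (i in pick) {
        tal <- as.integer(stats::rmultinom(1, sub$true_egg_count[i], probs))
        out[[length(out) + 1L]] <- data.frame(
          mass_id = sub$mass_id[i], treatment = trt,
          n_undeveloped = tal[1], n_early = tal[2], n_late = tal[3],
          n_hatched = tal[4], stringsAsFactors = FALSE)
      }
    }
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(mass_id = character(), treatment = character(),
               n_undeveloped = integer(), n_early = integer(),
               n_late = integer(), n_hatched = integer(),
               stringsAsFactors = FALSE)
}

# Build the initial roster: ids, treatments and genotypes. Focals carry the
# private third allele homozygously so their paternity is unambiguous.
build_roster <- function(cfg) {
  partner_genos <- list(c("A", "A"), c("A", "B"), c("B", "B"))
  rows <- list()
  with_substream(substream_seed(cfg$seed, "roster"), {
    for (i in seq_len(cfg$n_groups_multi)) {
      gid <- sprintf("M%02d", i)
      for (j in seq_len(cfg$group_size)) {
        g <- if (j == 1L) c(FOCAL_ALLELE, FOCAL_ALLELE) else
          partner_genos[[sample.int(3L, 1L)]]
        rows[[length(rows) + 1L]] <- data.frame(
          snail_id = sprintf("%s_%d", gid, j), group_id = gid,
          treatment = "multiple", allele1 = g[1], allele2 = g[2],
          is_focal = j == 1L, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(cfg$n_pairs_single)) {
      gid <- sprintf("S%02d", i)
      for (j in 1:2) {
        g <- if (j == 1L) c(FOCAL_ALLELE, FOCAL_ALLELE) else
          partner_genos[[sample.int(3L, 1L)]]
        rows[[length(rows) + 1L]] <- data.frame(
          snail_id = sprintf("%s_%d", gid, j), group_id = gid,
          treatment = "single", allele1 = g[1], allele2 = g[2],
          is_focal = j == 1L, stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(cfg$n_isolated)) {
      gid <- sprintf("N%02d", i)
      g <- partner_genos[[sample.int(3L, 1L)]]
      rows[[length(rows) + 1L]] <- data.frame(
        snail_id = sprintf("%s_1", gid), group_id = gid,
        treatment = "none", allele1 = g[1], allele2 = g[2],
        is_focal = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ground-truth reproductive success through a cumulative week
#'
#' Oracle for recovery tests: the true cumulative female reproductive success
#' (eggs laid) and male reproductive success (eggs fathered, excluding selfed
#' eggs) of every snail, taken from the generator's paternity record.
#'
#' @param xp a `"snail_experiment"`.
#' @param week cumulative week (1..weeks).
#' @return data frame `snail_id`, `true_RS_m`, `true_RS_f`.
#' @export
ground_truth_summary <- function(xp, week) {
  cfg <- xp$config
  if (!(week %in% seq_len(cfg$weeks))) {
    stop(sprintf("unknown week %s (experiment has weeks 1..%d)",
                 week, cfg$weeks))
  }
  ids <- xp$roster$snail_id
  rs_f <- stats::setNames(rep(0, length(ids)), ids)
  rs_m <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(xp$masses) && nrow(xp$masses)) {
    keep <- xp$masses$week <= week
    mm <- xp$masses[keep, , drop = FALSE]
    agg <- tapply(mm$true_egg_count, mm$mother_id, sum)
    rs_f[names(agg)] <- agg
    pp <- xp$paternity[xp$paternity$mass_id %in% mm$mass_id &
                         xp$paternity$father_id != SELF_ID, , drop = FALSE]
    if (nrow(pp)) {
      aggm <- tapply(pp$n_eggs, pp$father_id, sum)
      rs_m[names(aggm)] <- aggm
    }
  }
  data.frame(snail_id = ids, true_RS_m = as.numeric(rs_m[ids]),
             true_RS_f = as.numeric(rs_f[ids]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.snail_experiment <- function(x, ...) {
  cat("Synthetic mating experiment\n")
  cat(sprintf("  %d snails, %d mating events, %d egg masses, %d genotyped eggs\n",
              nrow(x$roster), nrow(x$events),
              if (is.null(x$masses)) 0L else nrow(x$masses),
              nrow(x$genotypes)))
  cat(sprintf("  weeks: %d, seed: %d\n", x$config$weeks, x$config$seed))
  invisible(x)
}
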