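#' Configuration for a synthetic mating experiment
#'
#' Builds and validates the parameter set of the mating-system simulator. The
#' defaults reproduce the design of the eight-week pond-snail study the package
#' is modelled on: 25 groups of 5 snails with multiple partners, 25 pairs with
#' a single partner, 25 isolated (selfing) snails, two 7-hour mating trials per
#' week on days 1 and 4, fecundity of roughly 100-300 eggs per week laid in 1-4
#' egg masses, allosperm retained for about 62 days, and 10-24 eggs genotyped
#' per followed egg mass at one three-allele microsatellite locus.
#'
#' @param n_groups_multi number of multiple-partner groups.
#' @param group_size snails per multiple-partner group (>= 2); one focal each.
#' @param n_pairs_single number of single-partner pairs.
#' @param n_isolated number of no-partner (virgin, selfing) snails.
#' @param weeks experiment duration in weeks.
#' @param trials_per_week mating trials per week.
#' @param mating_rate mean copulations initiated per snail per trial
#'   (Poisson). The default 0.75 yields a cumulative mating success per role of
#'   about 3 by week 2 and about 12 by week 8, as observed in the study system.
#' @param role_bias probability the initiator of a copulation takes the male
#'   (sperm-donor) role.
#' @param fecundity_mean mean eggs laid per snail per week (negative binomial).
#' @param fecundity_dispersion negative-binomial size parameter of the weekly
#'   egg total; larger is closer to Poisson.
#' @param masses_per_week_range integer range (min, max) of egg masses over
#'   which a week's eggs are split.
#' @param sperm_retention_days days after which a stored sperm deposit is lost.
#' @param sperm_decay per-day retention fraction of stored sperm in (0, 1].
#' @param paternity_exponent exponent linking a donor's stored-sperm share to
#'   its fertilization odds: 0 gives random paternity among donors present, 1 a
#'   fair raffle proportional to stored amounts.
#' @param weekly_death_prob per-week death probability, identical across
#'   treatments.
#' @param genotyped_per_mass_range integer range of eggs genotyped per followed
#'   mass.
#' @param selfing_allowed if `TRUE`, snails with an empty allosperm store lay
#'   self-fertilized eggs (virgins self at the start of the experiment).
#' @param calibration_intercept,calibration_slope linear map from egg count to
#'   egg-mass length: `length_mm = intercept + slope * eggs` plus noise
#'   (millimetres; slope in mm per egg).
#' @param length_noise_sd standard deviation (mm) of the Gaussian noise on
#'   egg-mass length.
#' @param counted_per_stratum egg masses per treatment and week whose eggs are
#'   directly counted for the length calibration.
#' @param followed_weeks weeks in which one egg mass per multiple-partner
#'   mother is developed for offspring genotyping; `NULL` (default) uses weeks
#'   1, 2, 4, 6 and 8 clipped to the experiment length.
#' @param hatch_prob,undeveloped_prob named length-3 probability vectors
#'   (multiple, single, none) used when simulating 14-day developmental
#'   outcomes of end-of-experiment egg masses.
#' @param seed root RNG seed; per-group substreams are derived from it by
#'   stable hashing of group identifiers.
#' @return an object of class `"simulation_config"` (a validated list).
#' @examples
#' cfg <- simulation_config(n_groups_multi = 4, n_pairs_single = 2,
#'                          n_isolated = 2, seed = 7)
#' cfg$mating_rate
#' @export
simulation_config <- function(n_groups_multi = 25,
                              group_size = 5,
                              n_pairs_single = 25,
                              n_isolated = 25,
                              weeks = 8,
                              trials_per_week = 2,
                              mating_rate = 0.75,
                              role_bias = 0.5,
                              fecundity_mean = 200,
                              fecundity_dispersion = 20,
                              masses_per_week_range = c(1L, 4L),
                              sperm_retention_days = 62,
                              sperm_decay = 1,
                              paternity_exponent = 1,
                              weekly_death_prob = 0.025,
                              genotyped_per_mass_range = c(10L, 24L),
                              selfing_allowed = TRUE,
                              calibration_intercept = 5,
                              calibration_slope = 0.25,
                              length_noise_sd = 2,
                              counted_per_stratum = 24,
                              followed_weeks = NULL,
                              hatch_prob = c(multiple = 0.85, single = 0.80, none = 0.70),
                              undeveloped_prob = c(multiple = 0.08, single = 0.12, none = 0.22),
                              seed = 1L) {
  if (is.null(followed_weeks)) {
    followed_weeks <- intersect(c(1L, 2L, 4L, 6L, 8L), seq_len(weeks))
  }
  cfg <- list(
    n_groups_multi = as.integer(n_groups_multi),
    group_size = as.integer(group_size),
    n_pairs_single = as.integer(n_pairs_single),
    n_isolated = as.integer(n_isolated),
    weeks = as.integer(weeks),
    trials_per_week = as.integer(trials_per_week),
    mating_rate = as.numeric(mating_rate),
    role_bias = as.numeric(role_bias),
    fecundity_mean = as.numeric(fecundity_mean),
    fecundity_dispersion = as.numeric(fecundity_dispersion),
    masses_per_week_range = as.integer(masses_per_week_range),
    sperm_retention_days = as.numeric(sperm_retention_days),
    sperm_decay = as.numeric(sperm_decay),
    paternity_exponent = as.numeric(paternity_exponent),
    weekly_death_prob = as.numeric(weekly_death_prob),
    genotyped_per_mass_range = as.integer(genotyped_per_mass_range),
    selfing_allowed = isTRUE(selfing_allowed),
    calibration_intercept = as.numeric(calibration_intercept),
    calibration_slope = as.numeric(calibration_slope),
    length_noise_sd = as.numeric(length_noise_sd),
    counted_per_stratum = as.integer(counted_per_stratum),
    followed_weeks = as.integer(followed_weeks),
    hatch_prob = hatch_prob,
    undeveloped_prob = undeveloped_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks ranges and orderings of all fields; errors name the offending field.
#'
#' @param cfg a `"simulation_config"` object or compatible list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  check_field(cfg$n_groups_multi >= 0, "n_groups_multi", "must be >= 0")
  check_field(cfg$group_size >= 2, "group_size",
              "must be >= 2 for mated treatments")
  check_field(cfg$n_pairs_single >= 0, "n_pairs_single", "must be >= 0")
  check_field(cfg$n_isolated >= 0, "n_isolated", "must be >= 0")
  check_field(cfg$weeks >= 1, "weeks", "must be >= 1")
  check_field(cfg$trials_per_week >= 1, "trials_per_week", "must be >= 1")
  check_field(cfg$mating_rate >= 0, "mating_rate", "must be non-negative")
  check_field(cfg$role_bias >= 0 && cfg$role_bias <= 1, "role_bias",
              "must be a probability in [0, 1]")
  check_field(cfg$fecundity_mean > 0, "fecundity_mean", "must be positive")
  check_field(cfg$fecundity_dispersion > 0, "fecundity_dispersion",
              "must be positive")
  check_field(length(cfg$masses_per_week_range) == 2 &&
                cfg$masses_per_week_range[1] >= 1 &&
                cfg$masses_per_week_range[1] <= cfg$masses_per_week_range[2],
              "masses_per_week_range", "must be an ordered pair with min >= 1")
  check_field(cfg$sperm_retention_days > 0, "sperm_retention_days",
              "must be positive")
  check_field(cfg$sperm_decay > 0 && cfg$sperm_decay <= 1, "sperm_decay",
              "must lie in (0, 1]")
  check_field(cfg$paternity_exponent >= 0, "paternity_exponent",
              "must be >= 0")
  check_field(cfg$weekly_death_prob >= 0 && cfg$weekly_death_prob <= 1,
              "weekly_death_prob", "must be a probability in [0, 1]")
  check_field(length(cfg$genotyped_per_mass_range) == 2 &&
                cfg$genotyped_per_mass_range[1] >= 1 &&
                cfg$genotyped_per_mass_range[1] <= cfg$genotyped_per_mass_range[2],
              "genotyped_per_mass_range", "must be an ordered pair with min >= 1")
  check_field(cfg$calibration_slope > 0, "calibration_slope",
              "must be positive")
  check_field(cfg$length_noise_sd >= 0, "length_noise_sd",
              "must be non-negative")
  check_field(cfg$counted_per_stratum >= 0, "counted_per_stratum",
              "must be >= 0")
  check_field(all(cfg$followed_weeks >= 1 & cfg$followed_weeks <= cfg$weeks),
              "followed_weeks", "must lie in 1..weeks")
  check_field(all(cfg$hatch_prob >= 0 & cfg$hatch_prob <= 1) &&
                length(cfg$hatch_prob) == 3,
              "hatch_prob", "must be three probabilities")
  check_field(all(cfg$undeveloped_prob >= 0 & cfg$undeveloped_prob <= 1) &&
                length(cfg$undeveloped_prob) == 3 &&
                all(cfg$hatch_prob + cfg$undeveloped_prob <= 1),
              "undeveloped_prob",
              "must be three probabilities with hatch + undeveloped <= 1")
  check_field(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Mating-experiment simulation configuration\n")
  cat(sprintf("  treatments: %d groups of %d (multiple), %d pairs (single), %d isolated\n",
              x$n_groups_multi, x$group_size, x$n_pairs_single, x$n_isolated))
  cat(sprintf("  schedule:   %d weeks x %d trials/week\n", x$weeks, x$trials_per_week))
  cat(sprintf("  mating:     rate %.2f/snail/trial, role bias %.2f\n",
              x$mating_rate, x$role_bias))
  cat(sprintf("  fecundity:  mean %.0f eggs/week in %d-%d masses\n",
              x$fecundity_mean, x$masses_per_week_range[1], x$masses_per_week_range[2]))
  cat(sprintf("  sperm:      retention %.0f d, decay %.3f/d, paternity exponent %.2f\n",
              x$sperm_retention_days, x$sperm_decay, x$paternity_exponent))
  cat(sprintf("  seed:       %d\n", x$seed))
  invisible(x)
}
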