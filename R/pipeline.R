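# Pipeline: delimited-text I/O for the experiment tables, schema validation
# with per-row diagnostics, cohort mortality bookkeeping, and the end-to-end
# orchestration that writes the report bundle.

#' Write an experiment's tables as delimited text
#'
#' Writes `events.csv`, `masses.csv`, `genotypes.csv`, `roster.csv`,
#' `development.csv`, `truth.csv` (ground-truth paternity, for testing only)
#' and `config.yaml` into a directory.
#'
#' @param xp a `"snail_experiment"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(xp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  ev <- xp$events[, c("event_id", "group_id", "week", "trial", "donor_id",
                      "recipient_id")]
  wr(ev, "events.csv")
  ms <- xp$masses[, c("mass_id", "mother_id", "group_id", "treatment", "week",
                      "length_mm", "counted_eggs", "followed")]
  wr(ms, "masses.csv")
  wr(xp$genotypes, "genotypes.csv")
  ro <- xp$roster[, c("snail_id", "group_id", "treatment", "allele1",
                      "allele2", "is_focal", "death_week")]
  wr(ro, "roster.csv")
  wr(xp$development, "development.csv")
  wr(xp$paternity, "truth.csv")
  cfg <- xp$config
  cfg$hatch_prob <- as.list(cfg$hatch_prob)
  cfg$undeveloped_prob <- as.list(cfg$undeveloped_prob)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read experiment tables from a directory
#'
#' Inverse of [write_dataset()]; reconstructs a `"snail_experiment"`-shaped
#' list (without the per-mass ground-truth columns unless `truth.csv` is
#' present).
#'
#' @param dir directory holding the CSV tables and `config.yaml`.
#' @return a `"snail_experiment"` object.
#' @export
read_dataset <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  cfgl <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(simulation_config, c(
    cfgl[setdiff(names(cfgl), c("hatch_prob", "undeveloped_prob"))],
    list(hatch_prob = unlist(cfgl$hatch_prob),
         undeveloped_prob = unlist(cfgl$undeveloped_prob))))
  masses <- rd("masses.csv")
  masses$counted <- !is.na(masses$counted_eggs)
  roster <- rd("roster.csv")
  deaths <- roster[!is.na(roster$death_week), c("snail_id", "death_week")]
  names(deaths) <- c("snail_id", "week")
  rownames(deaths) <- NULL
  paternity <- if (file.exists(file.path(dir, "truth.csv"))) rd("truth.csv")
  else NULL
  structure(list(roster = roster, events = rd("events.csv"), masses = masses,
                 paternity = paternity, genotypes = rd("genotypes.csv"),
                 development = rd("development.csv"), deaths = deaths,
                 config = cfg),
            class = "snail_experiment")
}

#' Validate experiment tables
#'
#' Checks referential integrity (all identifiers resolve) and domain rules
#' (weeks in range, donor and recipient distinct, no events after a snail's
#' death week, non-negative lengths) and returns per-row diagnostics.
#'
#' @param xp a `"snail_experiment"` or compatible list of tables.
#' @return data frame `table`, `row`, `problem`; zero rows when the dataset is
#'   valid.
#' @export
validate_inputs <- function(xp) {
  diag <- list()
  note <- function(tab, row, problem) {
    diag[[length(diag) + 1L]] <<- data.frame(table = tab, row = row,
                                             problem = problem,
                                             stringsAsFactors = FALSE)
  }
  ids <- xp$roster$snail_id
  weeks <- xp$config$weeks
  dw <- stats::setNames(xp$roster$death_week, xp$roster$snail_id)
  ev <- xp$events
  for (i in seq_len(nrow(ev))) {
    if (ev$donor_id[i] == ev$recipient_id[i]) {
      note("events", i, "donor equals recipient")
    }
    for (col in c("donor_id", "recipient_id")) {
      if (!ev[[col]][i] %in% ids) {
        note("events", i, sprintf("unknown %s '%s'", col, ev[[col]][i]))
      }
    }
    if (ev$week[i] < 1 || ev$week[i] > weeks) note("events", i, "week out of range")
    for (col in c("donor_id", "recipient_id")) {
      d <- unname(dw[ev[[col]][i]])
      if (length(d) == 1 && !is.na(d) && ev$week[i] >= d) {
        note("events", i, sprintf("%s '%s' dead from week %d", col,
                                  ev[[col]][i], d))
      }
    }
  }
  ms <- xp$masses
  for (i in seq_len(nrow(ms))) {
    if (!ms$mother_id[i] %in% ids) {
      note("masses", i, sprintf("unknown mother '%s'", ms$mother_id[i]))
    }
    if (ms$week[i] < 1 || ms$week[i] > weeks) note("masses", i, "week out of range")
    if (ms$length_mm[i] < 0) note("masses", i, "negative length")
  }
  gt <- xp$genotypes
  for (i in seq_len(nrow(gt))) {
    if (!gt$mass_id[i] %in% ms$mass_id) {
      note("genotypes", i, sprintf("unknown mass '%s'", gt$mass_id[i]))
    }
  }
  if (length(diag)) do.call(rbind, diag) else
    data.frame(table = character(), row = integer(), problem = character(),
               stringsAsFactors = FALSE)
}

#' Treatment mortality bookkeeping
#'
#' Percentage of snails that died per treatment, from dead and total counts,
#' rounded to whole percent as conventionally reported.
#'
#' @param dead,total integer vectors (same length), optionally named by
#'   treatment.
#' @return data frame `treatment`, `dead`, `total`, `percent`.
#' @export
mortality_percentages <- function(dead, total) {
  if (length(dead) != length(total)) stop("dead and total differ in length")
  if (any(dead > total)) stop("dead exceeds total")
  trt <- if (!is.null(names(dead))) names(dead) else
    paste0("treatment", seq_along(dead))
  data.frame(treatment = trt, dead = as.integer(dead),
             total = as.integer(total),
             percent = round(100 * dead / total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort mortality summary of an experiment
#'
#' Counts deaths per treatment from the roster and reports the percentages via
#' [mortality_percentages()], plus overall survival.
#'
#' @param roster roster table with `treatment` and `death_week`.
#' @return list with `by_treatment` data frame and `overall_survival_percent`.
#' @export
mortality_summary <- function(roster) {
  dead <- tapply(!is.na(roster$death_week), roster$treatment, sum)
  total <- tapply(rep(1L, nrow(roster)), roster$treatment, sum)
  by_trt <- mortality_percentages(stats::setNames(as.integer(dead), names(dead)),
                                  as.integer(total))
  list(by_treatment = by_trt,
       overall_survival_percent =
         round(100 * (1 - sum(dead) / sum(total)), 1))
}

#' Run configuration for the full pipeline
#'
#' @param simulate if `TRUE`, generate the input dataset from `sim_config`;
#'   otherwise read it from `input_dir`.
#' @param sim_config a [simulation_config()] (when simulating).
#' @param input_dir directory of input tables (when not simulating).
#' @param weeks weeks to report (default all).
#' @param bootstrap_reps bootstrap resamples for the confidence intervals.
#' @param seed analysis seed (bootstrap resampling).
#' @param out_dir report output directory.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(simulate = TRUE, sim_config = simulation_config(),
                       input_dir = NULL, weeks = NULL,
                       bootstrap_reps = 1000L, seed = 1L, out_dir = "report") {
  if (!simulate && (is.null(input_dir) || !dir.exists(input_dir))) {
    stop("input_dir must exist when simulate = FALSE")
  }
  structure(list(simulate = isTRUE(simulate), sim_config = sim_config,
                 input_dir = input_dir, weeks = weeks,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the experiment tables, validates them, tabulates
#' per-focal success records, fits the paternity regression, computes the
#' weekly selection metrics and gradients, fits the repeated-measures mixed
#' models and the mating-mode model, tests developmental outcomes, and writes
#' the report bundle: `metrics_by_week.csv`, `gradients_by_week.csv`,
#' `slope_comparisons.csv`, `mixed_models.csv`, `outcomes.csv`,
#' `mortality.csv` and a `manifest.json` run record. Reruns with the same
#' inputs and seed are identical.
#'
#' @param rc a [run_config()].
#' @return invisibly, a list with all computed tables and fitted objects.
#' @export
run_pipeline <- function(rc) {
  xp <- if (rc$simulate) simulate_experiment(rc$sim_config) else
    read_dataset(rc$input_dir)
  diag <- validate_inputs(xp)
  if (nrow(diag)) {
    stop(sprintf("input validation failed with %d problem(s); first: %s row %d: %s",
                 nrow(diag), diag$table[1], diag$row[1], diag$problem[1]))
  }
  records <- build_success_records(xp, weeks = rc$weeks)
  fit <- fit_sexual_selection(records, weeks = rc$weeks,
                              bootstrap_reps = rc$bootstrap_reps,
                              seed = rc$seed)
  slopes <- do.call(rbind, lapply(c("beta_mm", "beta_fPC1"), function(l) {
    slope_comparison_table(fit, l)
  }))

  rel <- fit$relative
  mixed <- list()
  if (!is.null(rel) && !anyNA(rel$rel_RS_m)) {
    mixed$male <- fit_weekly_mixed_model(
      rel, mixed_model_spec("rel_RS_m", c("rel_MS_m", "rel_MS_f")))
    mixed$female <- fit_weekly_mixed_model(
      rel, mixed_model_spec("rel_RS_f", c("rel_MS_m", "rel_MS_f")))
  }
  mixed$mating_mode <- mating_mode_model(records)
  mixed$quality <- if (!anyNA(records$RS_m)) quality_correlation_model(records)
  else NULL
  mixed_tab <- do.call(rbind, lapply(names(Filter(Negate(is.null), mixed)),
                                     function(nm) {
    cbind(model = nm, mixed[[nm]]$tests, stringsAsFactors = FALSE)
  }))

  tal <- tally_development(xp$development)
  chi <- chi_square_outcomes(tal$totals)
  wlc <- rbind(pairwise_outcome_tests(tal$proportions, "hatched"),
               pairwise_outcome_tests(tal$proportions, "undeveloped"))
  outcomes_tab <- rbind(
    data.frame(test = "chi_square_all", treatment1 = NA, treatment2 = NA,
               category = "all", statistic = chi[["chisq"]], p = chi[["p"]],
               stringsAsFactors = FALSE),
    data.frame(test = "wilcoxon", treatment1 = wlc$treatment1,
               treatment2 = wlc$treatment2, category = wlc$category,
               statistic = wlc$Z, p = wlc$p, stringsAsFactors = FALSE))

  mort <- mortality_summary(xp$roster)

  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(rc$out_dir, f),
                                        row.names = FALSE)
  wr(fit$metrics, "metrics_by_week.csv")
  wr(fit$gradients, "gradients_by_week.csv")
  wr(slopes, "slope_comparisons.csv")
  wr(mixed_tab, "mixed_models.csv")
  wr(outcomes_tab, "outcomes.csv")
  wr(mort$by_treatment, "mortality.csv")
  manifest <- list(
    package = "hermsel",
    version = as.character(utils::packageVersion("hermsel")),
    seed = rc$seed, bootstrap_reps = rc$bootstrap_reps,
    simulated = rc$simulate,
    config_hash = if (rc$simulate) config_hash(rc$sim_config) else NA,
    tables = c("metrics_by_week.csv", "gradients_by_week.csv",
               "slope_comparisons.csv", "mixed_models.csv", "outcomes.csv",
               "mortality.csv"))
  jsonlite::write_json(manifest, file.path(rc$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(experiment = xp, records = records, fit = fit,
                 slope_comparisons = slopes, mixed = mixed,
                 outcomes = outcomes_tab, mortality = mort,
                 manifest = manifest))
}

# Deterministic hash of a configuration (stable across runs and platforms).
config_hash <- function(cfg) {
  s <- paste(names(unclass(cfg)),
             vapply(unclass(cfg), function(v) paste(format(v, digits = 15),
                                                    collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  sprintf("%08x", stable_hash(s))
}
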