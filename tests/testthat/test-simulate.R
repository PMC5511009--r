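# The synthetic experiment generator: design coverage, seeded determinism,
# sperm-store bookkeeping and the paternity accounting identities.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(role_bias = 1.5), "role_bias")
  expect_error(simulation_config(group_size = 1), "group_size")
  expect_error(simulation_config(sperm_decay = 0), "sperm_decay")
  expect_error(simulation_config(masses_per_week_range = c(4, 1)),
               "masses_per_week_range")
  expect_error(simulation_config(weekly_death_prob = -0.1), "weekly_death_prob")
})

test_that("a seeded run is deterministic and covers the three treatments", {
  cfg <- small_config()
  xp1 <- small_experiment()$xp
  xp2 <- simulate_experiment(cfg)
  expect_identical(xp1[setdiff(names(xp1), "config")],
                   xp2[setdiff(names(xp2), "config")])
  expect_setequal(unique(xp1$roster$treatment),
                  c("multiple", "single", "none"))
  # no-partner snails never appear in mating events
  none_ids <- xp1$roster$snail_id[xp1$roster$treatment == "none"]
  expect_false(any(xp1$events$donor_id %in% none_ids |
                     xp1$events$recipient_id %in% none_ids))
  # ... and their masses are all self-fertilized
  none_masses <- xp1$masses$mass_id[xp1$masses$mother_id %in% none_ids]
  pat_none <- xp1$paternity[xp1$paternity$mass_id %in% none_masses, ]
  expect_true(all(pat_none$father_id == "SELF"))
  # no mating events involve a snail at or after its death week
  dw <- setNames(xp1$roster$death_week, xp1$roster$snail_id)
  for (col in c("donor_id", "recipient_id")) {
    lim <- dw[xp1$events[[col]]]
    expect_true(all(is.na(lim) | xp1$events$week < lim))
  }
})

test_that("degenerate rates behave as specified", {
  xp0 <- simulate_experiment(small_config(mating_rate = 0))
  expect_identical(nrow(xp0$events), 0L)
  gt <- ground_truth_summary(xp0, 4)
  expect_true(all(gt$true_RS_m == 0))
  expect_true(any(gt$true_RS_f > 0))  # selfing still yields eggs

  xp_alive <- simulate_experiment(small_config(weekly_death_prob = 0))
  expect_identical(nrow(xp_alive$deaths), 0L)
})

test_that("initiator takes the male role with the configured probability", {
  set.seed(42)
  ev <- do.call(rbind, lapply(1:2000, function(i) {
    simulate_mating_trial(c("a", "b", "c"), 1, 1, mating_rate = 1,
                          role_bias = 0.5)
  }))
  frac <- mean(ev$donor_id == ev$initiator_id)
  se <- sqrt(0.25 / nrow(ev))
  expect_lt(abs(frac - 0.5), 3 * se)
  # role_bias = 1: the initiator is always the donor
  set.seed(43)
  ev1 <- simulate_mating_trial(letters[1:4], 1, 1, mating_rate = 5,
                               role_bias = 1)
  expect_true(all(ev1$donor_id == ev1$initiator_id))
  # fewer than two snails: no events, not an error
  expect_identical(nrow(simulate_mating_trial("a", 1, 1, 5)), 0L)
})

test_that("sperm store obeys decay, retention and share accounting", {
  s <- new_sperm_store()
  s <- update_sperm_store(s, c("d1", "d1", "d1", "d2"), day = 1,
                          decay = 1, retention_days = Inf)
  sh <- store_shares(s)
  expect_equal(unname(sh["d1"] / sum(sh)), 0.75)
  expect_equal(unname(sh["d2"] / sum(sh)), 0.25)
  # with no decay, stored amount equals the number of matings received
  expect_equal(unname(sh["d1"]), 3)

  # a deposit is dropped once older than the retention limit
  s2 <- update_sperm_store(new_sperm_store(), "d1", day = 0,
                           decay = 1, retention_days = 62)
  s2 <- update_sperm_store(s2, character(0), day = 63,
                           decay = 1, retention_days = 62)
  expect_identical(length(s2$amount), 0L)
  # exponential decay halves the amount at the configured rate
  s3 <- update_sperm_store(new_sperm_store(), "d1", day = 0,
                           decay = 0.5, retention_days = Inf)
  s3 <- update_sperm_store(s3, character(0), day = 3,
                           decay = 0.5, retention_days = Inf)
  expect_equal(s3$amount, 0.125)
  # time cannot run backwards
  expect_error(update_sperm_store(s3, character(0), day = 1), "negative")
})

test_that("oviposition draws fathers multinomially from stored-sperm shares", {
  cfg <- small_config(fecundity_mean = 10000, masses_per_week_range = c(1, 1),
                      paternity_exponent = 1)
  store <- new_sperm_store()
  store <- update_sperm_store(store, c(rep("dA", 4), "dB"), day = 1)
  set.seed(7)
  mm <- simulate_oviposition("mo", store, week = 1, cfg)
  pat <- mm$paternity[[1]]
  n <- sum(pat)
  fracA <- pat[["dA"]] / n
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(fracA - 0.8), 3 * se)

  # a single donor fathers everything; an empty store means selfing
  store1 <- update_sperm_store(new_sperm_store(), "solo", day = 1)
  set.seed(8)
  m1 <- simulate_oviposition("mo", store1, 1, cfg)
  expect_identical(names(m1$paternity[[1]]), "solo")
  set.seed(9)
  m0 <- simulate_oviposition("mo", new_sperm_store(), 1, cfg)
  expect_identical(names(m0$paternity[[1]]), "SELF")
  # with selfing disallowed and no allosperm, no eggs are laid
  cfg_ns <- small_config(selfing_allowed = FALSE)
  set.seed(10)
  expect_identical(nrow(simulate_oviposition("mo", new_sperm_store(), 1,
                                             cfg_ns)), 0L)
})

test_that("per-mass lengths are monotone in egg count within treatment-week", {
  xp <- small_experiment()$xp
  by <- split(xp$masses, list(xp$masses$treatment, xp$masses$week),
              drop = TRUE)
  for (b in by) {
    o <- order(b$true_egg_count)
    expect_true(all(diff(b$length_mm[o]) >= 0))
  }
})

test_that("paternity accounting conserves eggs globally and per pair", {
  xp <- small_experiment()$xp
  # per mass the father counts sum to the egg count
  per_mass <- tapply(xp$paternity$n_eggs, xp$paternity$mass_id, sum)
  expect_equal(as.vector(per_mass[xp$masses$mass_id]),
               xp$masses$true_egg_count)
  # globally: outcrossed + selfed = all eggs laid
  gt <- ground_truth_summary(xp, xp$config$weeks)
  selfed <- sum(xp$paternity$n_eggs[xp$paternity$father_id == "SELF"])
  expect_equal(sum(gt$true_RS_m) + selfed, sum(gt$true_RS_f))
  # in a pair, one snail's true RS_m equals its partner's outcrossed RS_f
  singles <- xp$roster[xp$roster$treatment == "single", ]
  for (gid in unique(singles$group_id)) {
    pair <- singles$snail_id[singles$group_id == gid]
    for (i in 1:2) {
      partner <- pair[3 - i]
      pm <- xp$masses$mass_id[xp$masses$mother_id == partner]
      outcrossed <- sum(xp$paternity$n_eggs[
        xp$paternity$mass_id %in% pm & xp$paternity$father_id != "SELF"])
      expect_equal(gt$true_RS_m[gt$snail_id == pair[i]], outcrossed)
    }
  }
  expect_error(ground_truth_summary(xp, 99), "unknown week")
})
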