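# Paternity scoring at one three-allele locus, the share regression with
# overdispersion correction, and male reproductive-success extrapolation.

test_that("paternity classes follow the possible paternal origins", {
  # focal homozygous for the private allele: scoring is unambiguous
  eggs <- rbind(c("A", "C"), c("C", "B"), c("A", "B"), c("B", "B"))
  res <- assign_paternity(eggs, mother = c("A", "B"), focal = c("C", "C"),
                          partner_alleles = c("A", "B"))
  expect_equal(as.character(res$class),
               c("focal", "focal", "nonfocal", "nonfocal"))
  expect_equal(res$n_ambiguous, 0L)

  # an egg sharing no allele with its mother flags data corruption
  expect_error(assign_paternity(rbind(c("B", "C")), mother = c("A", "A"),
                                focal = c("C", "C"),
                                partner_alleles = c("A", "B")),
               "shares no allele")

  # when the mother carries the focal allele, some eggs become ambiguous:
  # egg C/A can be (maternal C, partner A) or (maternal A, focal C)
  res2 <- assign_paternity(rbind(c("C", "A"), c("C", "B"), c("C", "C")),
                           mother = c("A", "C"), focal = c("C", "C"),
                           partner_alleles = c("A", "B"))
  expect_equal(as.character(res2$class), c("ambiguous", "nonfocal", "focal"))
})

test_that("scoring simulated eggs with known fathers reproduces the truth", {
  set.seed(31)
  mother <- c("A", "B")
  focal <- c("C", "C")
  partners <- list(c("A", "A"), c("A", "B"), c("B", "B"))
  truth <- character(200); eggs <- matrix("", 200, 2)
  for (i in 1:200) {
    if (runif(1) < 0.3) {
      truth[i] <- "focal"; fg <- focal
    } else {
      truth[i] <- "nonfocal"; fg <- partners[[sample.int(3, 1)]]
    }
    eggs[i, ] <- c(sample(mother, 1), sample(fg, 1))
  }
  res <- assign_paternity(eggs, mother, focal, partner_alleles = c("A", "B"))
  expect_equal(as.character(res$class), truth)
})

test_that("female mating shares partition the mother's received matings", {
  ev <- data.frame(week = c(1, 1, 2, 2),
                   donor_id = c("P1", "P2", "P3", "P1"),
                   recipient_id = "M")
  expect_equal(female_mating_share(ev, "M", "P1", 1), 0.5)
  expect_equal(female_mating_share(ev, "M", "P1", 2), 0.5)
  expect_equal(female_mating_share(ev, "M", "P3", 2), 0.25)
  expect_equal(female_mating_share(ev, "never", "P1", 2), 0)
  shares <- vapply(c("P1", "P2", "P3"), function(f)
    female_mating_share(ev, "M", f, 2), numeric(1))
  expect_equal(sum(shares), 1)
})

test_that("the share regression recovers known logistic parameters", {
  set.seed(77)
  a <- -1.2; b <- 2.5
  x <- runif(40)
  n <- rep(50L, 40)
  k <- rbinom(40, n, plogis(a + b * x))
  fit <- fit_paternity_glm(data.frame(x = x, k = k, n = n))
  expect_lt(abs(coef(fit)[["intercept"]] - a), 3 * fit$se[["intercept"]])
  expect_lt(abs(coef(fit)[["slope"]] - b), 3 * fit$se[["slope"]])
  expect_gt(fit$lr_stat, 10)  # strong association, as designed

  # flat half-and-half data: zero slope, prediction 0.5 everywhere
  flat <- data.frame(x = seq(0, 1, length.out = 10), k = 25L, n = 50L)
  f0 <- fit_paternity_glm(flat)
  expect_equal(coef(f0)[["slope"]], 0, tolerance = 1e-8)
  expect_equal(unname(predict(f0, c(0, 0.5, 1))), rep(0.5, 3),
               tolerance = 1e-8)

  expect_error(fit_paternity_glm(data.frame(x = rep(0.5, 5), k = 1, n = 4)),
               "distinct x")
  sep <- fit_paternity_glm(data.frame(x = c(0.1, 0.9), k = 0L, n = 20L))
  expect_true(sep$separation)
})

test_that("binomial data yield a dispersion estimate near one", {
  set.seed(12)
  x <- runif(100)
  n <- rep(30L, 100)
  k <- rbinom(100, n, plogis(-0.5 + 1.5 * x))
  fit <- fit_paternity_glm(data.frame(x = x, k = k, n = n))
  expect_gt(fit$dispersion, 0.7)
  expect_lt(fit$dispersion, 1.4)
})

test_that("scaled standard errors keep coverage under overdispersion", {
  # beta-binomial eggs: true phi > 1; 95% Wald intervals for the slope should
  # still cover the truth at close to nominal rate
  set.seed(55)
  a <- -0.5; b <- 1.8
  cover <- vapply(1:200, function(r) {
    x <- runif(30)
    n <- rep(40L, 30)
    p <- plogis(a + b * x)
    rho <- 8  # beta-binomial concentration: phi around 5
    pp <- rbeta(30, p * rho, (1 - p) * rho)
    k <- rbinom(30, n, pp)
    fit <- tryCatch(fit_paternity_glm(data.frame(x = x, k = k, n = n)),
                    error = function(e) NULL)
    if (is.null(fit) || isTRUE(fit$separation)) return(NA)
    abs(coef(fit)[["slope"]] - b) < 1.96 * fit$se[["slope"]]
  }, logical(1))
  expect_gte(mean(cover, na.rm = TRUE), 0.90)
})

test_that("predictions are the inverse-logit of the linear predictor", {
  fit <- structure(list(coefficients = c(intercept = -0.8, slope = 2.1)),
                   class = "paternity_glm")
  xs <- seq(0, 1, by = 0.1)
  expect_equal(unname(predict(fit, xs)), 1 / (1 + exp(-(-0.8 + 2.1 * xs))))
  expect_true(all(diff(predict(fit, xs)) >= 0))  # monotone for positive slope
  expect_identical(predict_paternity_share(fit, 0.3), predict(fit, 0.3))
  expect_error(predict(fit, 1.2), "0, 1")
})

test_that("complete genotyping recovers true male success exactly", {
  # every mass followed and fully genotyped, every mass directly counted
  cfg <- small_config(masses_per_week_range = c(1, 1),
                      followed_weeks = 1:4,
                      genotyped_per_mass_range = c(100000L, 100000L),
                      counted_per_stratum = 100000L)
  xp <- simulate_experiment(cfg)
  masses <- estimate_egg_counts(xp$masses)
  samples <- genotype_samples(xp$genotypes, masses, xp$roster)
  gt <- ground_truth_summary(xp, 4)
  focals <- xp$roster$snail_id[xp$roster$is_focal &
                                 xp$roster$treatment == "multiple"]
  for (f in focals) {
    est <- male_reproductive_success(masses, samples, NULL, xp$events,
                                     xp$roster, f, 4)
    expect_equal(est, gt$true_RS_m[gt$snail_id == f])
  }
})

test_that("a predicted share fills in non-genotyped masses", {
  masses <- data.frame(mass_id = c("m1", "m2"), mother_id = "P",
                       week = c(1, 1), egg_count = c(100, 200))
  roster <- data.frame(snail_id = c("F", "P"), group_id = "g",
                       is_focal = c(TRUE, FALSE))
  samples <- data.frame(mass_id = "m1", n_genotyped = 10L, n_focal = 5L,
                        n_nonfocal = 5L, n_ambiguous = 0L)
  ev <- data.frame(week = 1, donor_id = "F", recipient_id = "P")
  model <- structure(list(coefficients = c(intercept = qlogis(0.25),
                                           slope = 0)),
                     class = "paternity_glm")
  # 0.5 * 100 observed + 0.25 * 200 predicted
  est <- male_reproductive_success(masses, samples, model, ev, roster, "F", 1)
  expect_equal(est, 50 + 50)
  # without a model the non-genotyped mass is an error
  expect_error(male_reproductive_success(masses, samples, NULL, ev, roster,
                                         "F", 1), "no paternity model")
})

test_that("estimated male success converges to the truth with sampling depth", {
  xp <- small_experiment()$xp
  masses <- estimate_egg_counts(xp$masses)
  gt <- ground_truth_summary(xp, 4)
  focals <- xp$roster$snail_id[xp$roster$is_focal &
                                 xp$roster$treatment == "multiple"]
  # build synthetic genotype samples at increasing sampling fractions by
  # hypergeometric draws from the true father composition of partner masses
  partner_masses <- masses[!masses$mother_id %in% focals &
                             masses$treatment == "multiple", ]
  mae <- c()
  set.seed(99)
  for (frac in c(0.25, 0.5, 1)) {
    samp <- do.call(rbind, lapply(seq_len(nrow(partner_masses)), function(i) {
      mid <- partner_masses$mass_id[i]
      pat <- xp$paternity[xp$paternity$mass_id == mid, ]
      fathers <- rep(pat$father_id, pat$n_eggs)
      n_g <- max(1L, round(frac * length(fathers)))
      pick <- sample(fathers, n_g)
      grp <- xp$roster$group_id[match(partner_masses$mother_id[i],
                                      xp$roster$snail_id)]
      foc <- xp$roster$snail_id[xp$roster$group_id == grp &
                                  xp$roster$is_focal]
      # selfed eggs cannot carry the focal's private allele, so they score as
      # non-focal in this constructed sample
      data.frame(mass_id = mid, n_genotyped = n_g,
                 n_focal = sum(pick == foc),
                 n_nonfocal = sum(pick != foc),
                 n_ambiguous = 0L)
    }))
    est <- vapply(focals, function(f)
      male_reproductive_success(masses[masses$treatment == "multiple", ],
                                samp, NULL, xp$events, xp$roster, f, 4),
      numeric(1))
    truth <- gt$true_RS_m[match(focals, gt$snail_id)]
    mae <- c(mae, mean(abs(est - truth)))
  }
  # exact at full sampling (up to calibration error in egg counts), improving
  # with depth
  expect_lt(mae[3], mae[1])
  expect_lt(mae[2], mae[1] * 1.5)
  est_cor <- suppressWarnings(cor(
    vapply(focals, function(f)
      male_reproductive_success(masses[masses$treatment == "multiple", ],
                                genotype_samples(xp$genotypes, masses,
                                                 xp$roster),
                                fit_paternity_glm(
                                  paternity_observations(
                                    genotype_samples(xp$genotypes, masses,
                                                     xp$roster),
                                    masses, xp$events, xp$roster)),
                                xp$events, xp$roster, f, 4), numeric(1)),
    gt$true_RS_m[match(focals, gt$snail_id)]))
  expect_gt(est_cor, 0.6)
})
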