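---
title: "Quantifying sexual selection over time in a simultaneous hermaphrodite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sexual selection over time in a simultaneous hermaphrodite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hermsel)
```

## The problem

In a simultaneous hermaphrodite every individual mates in two roles: as a
sperm donor (male role) and as a sperm recipient (female role). Sexual
selection can therefore act on both functions of the same body, and the two
are not independent — mating effort in one role may raise or depress
reproductive output in the other (cross-sex effects). The package quantifies
this from longitudinal observations of group-housed pond snails
(*Lymnaea stagnalis*): every copulation is observed and scored by role, eggs
are collected weekly, and a subsample of eggs is genotyped at one
microsatellite locus to attribute paternity.

Four success measures are tracked per focal individual and cumulative week:

* `MS_m`, `MS_f` — cumulative copulations performed in the male / female
  role (counts of matings, not of distinct mates; in small groups everyone
  soon mates with everyone, so mate number saturates while mating frequency
  keeps discriminating).
* `RS_f` — cumulative eggs laid, with egg counts of unmeasured masses
  calibrated from egg-mass length.
* `RS_m` — cumulative eggs fathered, estimated from partial genotyping.

From these, per cumulative week:

* the opportunity for selection `I = var(RS) / mean(RS)^2` and for sexual
  selection `I_s = var(MS) / mean(MS)^2`, each per role, with percentile
  bootstrap confidence intervals;
* the sexual selection gradients: least-squares slopes of relative RS on
  relative MS, within role (`beta_mm`, `beta_ff`) and across roles
  (`beta_mf`: male RS on female MS; `beta_fm`: female RS on male MS), both
  as bivariate fits and jointly in a two-predictor regression;
* the same gradients after replacing the two (correlated) mating-success
  measures by their principal components — PC1 the sexual bias, PC2 the
  overall mating activity;
* repeated-measures mixed models asking whether the gradients change across
  weeks.

All fitness measures are *relative*: divided by the mean of the living focal
cohort of that week, so the mean is 1 and `I` reduces to the sample variance.
The cohort is the set of living focals of the multiple-partner treatment;
focals that die are excluded from their death week onwards.

## Estimating male reproductive success

Complete genotyping of 100–300 eggs per snail per week is infeasible, so
`RS_m` is extrapolated. For each *followed* egg mass, 10–24 eggs are
genotyped; each egg carries one maternal and one paternal allele, and the
focal is homozygous for an allele its group partners do not carry, so a
focal-sired egg is recognized unambiguously (`assign_paternity()` also
handles the general case, scoring an egg ambiguous whenever both a focal and
a partner paternal origin could explain it). The focal's observed share of a
genotyped mass is `n_focal / (n_focal + n_nonfocal)`.

For non-genotyped masses the share is predicted from behaviour:
`fit_paternity_glm()` regresses the focal-fathered counts (`k` of `n`
assignable eggs, per mother and week) on the focal's share of that mother's
received matings, by logistic regression with the binomial totals as
weights. Overdispersion — expected, because eggs within a mass share a
fertilization history — is absorbed by scaling the standard errors with the
Pearson dispersion `phi = X^2 / (N - 2)` (quasi-likelihood). The focal's
`RS_m` is the sum over its partners' masses of (observed or predicted share)
× (egg count). Predicted shares are deliberately *not* renormalized across
candidate fathers: the calculation is per focal, so conservation of eggs is
exact for genotyped masses and only approximate for predicted ones.

The mating share entering both the model and its predictions is cumulated
through the week the mass was laid — the matings that could actually have
contributed sperm to it.

## The synthetic experiment generator

Because the original animal data are not redistributable, the package ships
a generator, `simulate_experiment()`, whose defaults are the study design
itself: 25 groups of 5 (multiple partners, one focal each), 25 pairs
(single partner), 25 isolated selfing snails; 8 weeks with two 7-hour
mating trials per week (days 1 and 4); and full ground-truth paternity
recorded for every egg, so every estimator in the package can be tested
against truth.

Stochastic components, and why their defaults look the way they do:

* **Copulations**: each living snail initiates `Poisson(mating_rate)`
  copulations per trial, partner uniform among living group members,
  initiator takes the male role with probability `role_bias` (0.5). Matings
  are unilateral; nothing forces a return mating. The default rate 0.75
  yields cumulative mating success near 3 by week 2 and near 12 by week 8
  per role, the magnitudes reported for this species.
* **Allosperm storage**: each received copulation deposits one unit of
  sperm; deposits decay by `sperm_decay` per day (default 1, no decay) and
  are discarded after `sperm_retention_days` (62 — about two months, the
  retention reported for the species). Eggs are laid at the end of each
  week.
* **Fecundity**: weekly egg totals are negative binomial (mean 200,
  dispersion 20 — most weeks fall in the species' typical 100–300 range),
  split over 1–4 masses.
* **Paternity**: each egg's father is drawn multinomially with odds
  proportional to `(stored amount)^paternity_exponent`. The default 1 is a
  fair raffle over stored sperm, matching the reported random use of stored
  allosperm. Exponent 0 is implemented as the *random-paternity calibration
  null* (the `0^0 = 1` reading of the odds): an inseminated mother's eggs
  take a father uniformly among her living partners, independent of who
  donated how often. Drawing uniformly over donors *present in the store*
  would not be a null: presence itself depends on mating, and eggs laid in
  the first weeks are fertilized before presence saturates, which alone
  produces a realized male gradient near 0.4. A never-inseminated mother
  selfs in either regime (selfing contributes only to `RS_f`).
* **Egg-mass length**: linear in egg count (5 mm + 0.25 mm/egg) plus
  Gaussian noise (SD 2 mm), recorded to the nearest 0.5 mm. Within each
  treatment-week stratum the noisy lengths are rank-matched to the egg
  counts, so length is monotone in count by construction while the marginal
  noise distribution is preserved. 24 masses per treatment and week are
  directly counted, which is what the length calibration is fitted on.
* **Mortality**: Bernoulli per week (0.025), independent of treatment —
  about 18% over eight weeks, matching the observed overall mortality. A
  death at the start of week *w* censors that focal's records from week *w*
  onwards.
* **Genotyping**: in weeks 1, 2, 4, 6 and 8 one mass per multiple-treatment
  mother is followed; 10–24 of its eggs are genotyped by sampling fathers
  without replacement from the mass's true composition.
* **Reproducibility**: one root seed; per-group substreams are derived by a
  stable string hash of the group identifier, so changing the number of
  groups does not reshuffle existing ones.

What the generator does **not** emulate: within-trial temporal structure
(chain copulations, role alternation within an encounter), partner
familiarity effects on mate choice, body-size growth or resource budgets,
and any treatment effect on mortality or fecundity. Passing recovery tests
on synthetic data therefore shows the estimators are consistent under the
generator's assumptions — not that real snails satisfy those assumptions.

## Numerical and inferential choices

* `I` and `I_s` use the sample (n−1) variance, the standard convention for
  opportunity-for-selection statistics.
* Bivariate gradients are computed in closed form (slope `cov/var`, the
  usual t-based inference); the test suite verifies exact agreement with
  `stats::lm`. The closed form keeps 1000-resample bootstraps of slopes
  cheap.
* Bootstrap intervals are percentile intervals over resampled focals
  (default 1000 resamples, seeded). For variance-type statistics at n = 25
  these undercover mildly: measured coverage for `I` under a lognormal
  model with known truth is about 86–89% at nominal 95%. They are reported
  as descriptive uncertainty, not exact frequentist intervals.
* The mating-success PCA is computed on the 2×2 correlation matrix (scale
  symmetry between the two roles), and components are labelled by their
  loading pattern, not their eigenvalue order: same-sign loadings = mating
  activity, opposite-sign = sexual bias, with the bias sign fixed so
  female-biased mating scores positive. Because the scores are orthogonal,
  the two bivariate PC gradients equal the joint two-predictor fit, and
  regression on both PCs reproduces the fitted values of the regression on
  both standardized mating-success columns — identities the tests check to
  1e-9.
* Two slopes are compared with `t = (b1 − b2)/sqrt(SE1^2 + SE2^2)` on
  `n1 + n2 − 4` df. Weekly cohorts overlap, so between-week comparisons are
  descriptive. No multiplicity adjustment is applied to the weekly gradient
  tests.
* The weekly mixed models are Gaussian, fitted by REML with a random
  intercept per focal; fixed-effect tests are marginal (type III) F-tests
  with Satterthwaite denominator degrees of freedom (hence fractional df).
  When the random-effect variance is estimated at zero the results coincide
  with ordinary least-squares ANOVA, which the tests verify to 1e-6; if the
  mixed fit fails outright the model falls back to that OLS path with a
  warning. Tukey-adjusted pairwise week comparisons come from estimated
  marginal means; the compact letter display is computed by insert-absorb.
* Developmental outcomes are compared by a Pearson chi-square on the
  treatment × category egg-count table and by pairwise rank-sum tests on
  per-mass proportions (the replication unit), using the normal
  approximation with tie *and* continuity corrections — the convention of
  mainstream statistical software. Against exact enumeration the
  approximation stays within 0.02 for group sizes of 5–8; below 5 the exact
  null distribution is too discrete for any normal approximation to track
  it that closely.
* Calibrated egg counts are `max(0, round(intercept + slope × length))`
  from the treatment-week stratum model, falling back to treatment-pooled
  and then global models when a stratum has fewer than two counted masses;
  direct counts always take precedence.

## Problem sizes in the test suite

The packaged checks run replicate studies at the design's own scale where
the property concerns the design (100 replicates of the 25-group
multiple-partner treatment for gradient calibration and the weekly decline
of `I_s`), and smaller seeded experiments (6 groups, 4 weeks) where the
property is algebraic or structural. Bootstrap calibrations use 300–400
replicates of 300–1000 resamples. These sizes are the package's choices for
stable yet routine runs of the full suite.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 1)
xp <- simulate_experiment(cfg)
records <- build_success_records(xp)
fit <- fit_sexual_selection(records, bootstrap_reps = 500, seed = 1)
summary(fit)
plot(fit, "beta_mm")

# how good is the paternity extrapolation? compare with the generator truth
gt <- ground_truth_summary(xp, 8)
wk8 <- records[records$week == 8, ]
cor(wk8$RS_m, gt$true_RS_m[match(wk8$focal_id, gt$snail_id)])
```

## Known limitations

* `RS_m` extrapolation inherits the biases of the share regression: shares
  are not renormalized across fathers, and selfed eggs in partners' masses
  inflate the denominator of nobody — totals are only approximately
  conserved for predicted masses.
* The weekly metrics are computed on overlapping cumulative windows;
  week-to-week differences are serially dependent and the slope-comparison
  t-tests treat them as independent samples.
* Percentile bootstrap intervals for `I` undercover mildly at cohort sizes
  around 25 (see above).
* The mixed models assume Gaussian responses; cumulative counts and
  calibrated egg numbers are treated as continuous, which is reasonable at
  these magnitudes but not exact.
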