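Package: hermsel
Title: Sexual Selection Gradients Over Time in Simultaneous Hermaphrodites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies pre- and post-copulatory sexual selection in
    simultaneously hermaphroditic animals followed over repeated mating
    trials, modelled on group-housed pond snails (Lymnaea stagnalis).
    Provides a seeded mating-system simulator with allosperm storage and
    multinomial fertilization, tabulation of cumulative male and female
    mating success and egg output (with egg-count calibration from egg-mass
    length), paternity assignment at a single microsatellite locus with
    extrapolation of male reproductive success through a weighted
    overdispersed binomial regression, opportunity-for-selection statistics
    and within- and cross-sex selection gradients (including a principal
    component reparametrization of collinear mating-success measures) with
    bootstrap confidence intervals, repeated-measures mixed models of the
    gradients across cumulative time windows, and treatment comparisons of
    offspring developmental outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    lmerTest,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
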