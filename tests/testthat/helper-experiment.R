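# Shared fixtures: small simulated experiments, cached per session so several
# test files can reuse them without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(...) {
  simulation_config(n_groups_multi = 6, n_pairs_single = 3, n_isolated = 3,
                    weeks = 4, seed = 101, ...)
}

# A cached small experiment plus its success records.
small_experiment <- function() {
  if (is.null(.fixture_env$xp)) {
    .fixture_env$xp <- simulate_experiment(small_config())
    .fixture_env$records <- build_success_records(.fixture_env$xp)
  }
  list(xp = .fixture_env$xp, records = .fixture_env$records)
}

# A cached full-design experiment (the emulated study's default conditions).
default_experiment <- function() {
  if (is.null(.fixture_env$xp_full)) {
    .fixture_env$xp_full <- simulate_experiment(simulation_config(seed = 2024))
    .fixture_env$records_full <- build_success_records(.fixture_env$xp_full)
  }
  list(xp = .fixture_env$xp_full, records = .fixture_env$records_full)
}

# Exact two-sided rank-sum p-value by complete enumeration of group
# assignments (oracle for the normal approximation).
exact_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  N <- length(all_v)
  n1 <- length(x)
  r <- rank(all_v)
  Wobs <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  Ws <- apply(utils::combn(N, n1), 2, function(ix) sum(r[ix]))
  mean(abs(Ws - mu) >= abs(Wobs - mu) - 1e-9)
}

# Balanced longitudinal data with the between-focal variance removed: the
# focal means of the residuals are exactly zero, so REML puts the random
# intercept on the boundary.
zero_focal_variance_data <- function(seed = 42, n_focal = 20, weeks = 8) {
  set.seed(seed)
  d <- data.frame(focal_id = rep(sprintf("f%02d", 1:n_focal), each = weeks),
                  week = rep(1:weeks, n_focal),
                  x = runif(n_focal * weeks))
  d$y <- 1 + 2 * d$x + rnorm(nrow(d))
  base <- lm(y ~ x * factor(week), data = d)
  r <- resid(base)
  d$y <- fitted(base) + r - ave(r, d$focal_id)
  d
}

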