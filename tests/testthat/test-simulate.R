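test_that("generator is bit-reproducible given a seed", {
  cfg <- sim_config(n_participants = 60, n_waves = 6, seed = 5)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a, b)
  c2 <- simulate_population(cfg, seed = 6)
  expect_false(identical(a, c2))
  # caller RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_population(cfg))
  expect_identical(before, .Random.seed)
})

test_that("Poisson limit: huge theta gives mean == variance == exp(b0)", {
  cfg <- flat_config(b0 = log(2), theta = 1e9, n = 1500, waves = 8)
  tab <- simulate_population(cfg)
  expect_equal(mean(tab$y), 2, tolerance = 0.03)
  expect_equal(var(tab$y), 2, tolerance = 0.05)
})

test_that("empirical moments match analytic NB2 moments on a large sample", {
  cfg <- flat_config(b0 = 0.5, theta = 1.5, n = 12500, waves = 8, seed = 3)
  tab <- simulate_population(cfg)
  expect_gte(nrow(tab), 1e5)
  mu <- exp(0.5)
  expect_equal(mean(tab$y), mu, tolerance = 0.02 * mu)
  expect_equal(var(tab$y), mu + mu^2 / 1.5,
               tolerance = 0.02 * (mu + mu^2 / 1.5))
})

test_that("moments match a brute-force NB-lognormal mixture oracle", {
  cfg <- flat_config(b0 = 0.5, theta = 1.5, n = 500, waves = 8, seed = 9,
                     sigma_p = 0.8)
  tab <- simulate_population(cfg)
  # oracle: 1e6 draws straight from the generative equations
  set.seed(1234)
  b <- rnorm(1e6, 0, 0.8)
  y_oracle <- pmin(rnbinom(1e6, mu = exp(0.5 + b), size = 1.5), 100)
  # empirical mean clusters by participant: compare at ~4 cluster SEs
  person_means <- tapply(tab$y, tab$participant_id, mean)
  se_mean <- sd(person_means) / sqrt(length(person_means))
  expect_equal(mean(tab$y), mean(y_oracle), tolerance = 4 * se_mean)
  expect_equal(var(tab$y), var(y_oracle), tolerance = 0.2 * var(y_oracle))
})

test_that("counts never exceed the cap", {
  cfg <- flat_config(b0 = 5, theta = 2, n = 300, waves = 4, seed = 2)
  tab <- simulate_population(cfg)
  expect_lte(max(tab$y), 100)
  expect_gt(mean(tab$y == 100), 0.1)  # the cap binds at mu ~ 150
})

test_that("participation matches a direct enumeration of the entry chain", {
  cfg <- sim_config(n_participants = 40000, n_waves = 3, seed = 21,
                    dropout_prob = 0.3, reentry_prob = 0.2,
                    entry_wave1_frac = 0.6)
  tab <- simulate_population(cfg)
  n_obs <- table(tab$participant_id)
  frac_2plus <- sum(n_obs >= 2) / cfg$n_participants
  # independent enumeration over entry wave and activity paths
  d <- 0.3; r <- 0.2; f <- 0.6; W <- 3
  probs <- c(f, rep((1 - f) / (W - 1), W - 1))
  p2 <- 0
  for (e in 1:W) {
    paths <- expand.grid(rep(list(c(TRUE, FALSE)), W - e))
    if (e == W) { p_more <- 0 } else {
      p_more <- 0
      for (i in seq_len(nrow(paths))) {
        st <- TRUE; pr <- 1
        for (w in seq_len(ncol(paths))) {
          nxt <- paths[i, w]
          pr <- pr * if (st) (if (nxt) 1 - d else d) else
            (if (nxt) r else 1 - r)
          st <- nxt
        }
        if (any(unlist(paths[i, ]))) p_more <- p_more + pr
      }
    }
    p2 <- p2 + probs[e] * p_more
  }
  expect_equal(frac_2plus, p2, tolerance = 0.01)
})

test_that("vaccination fields respect the rollout and the NA rule", {
  cfg <- sim_config(n_participants = 200, n_waves = 24, seed = 8)
  tab <- simulate_population(cfg)
  pre <- as.numeric(tab$report_date - cfg$origin) <
    cfg$vaccination_rollout_start_day
  expect_true(all(tab$vaccination_status[pre] == "not_available"))
  expect_identical(is.na(tab$first_dose_date),
                   is.na(tab$days_since_first_dose))
  expect_true(all(tab$first_dose_date - cfg$origin >=
                    cfg$vaccination_rollout_start_day, na.rm = TRUE))
  validate_survey(tab)
})

test_that("infection-status missingness concentrates in early waves", {
  cfg <- sim_config(n_participants = 600, n_waves = 12, seed = 13)
  tab <- simulate_population(cfg)
  early <- tab$wave_index <= cfg$infection_missing_wave_cut
  expect_gt(mean(is.na(tab$infection_status[early])), 0.8)
  expect_lt(mean(is.na(tab$infection_status[!early])), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(theta = 0), "theta")
  expect_error(sim_config(sigma_participant = -1), "SDs")
  expect_error(sim_config(dropout_prob = 1.2), "probabilities")
  expect_error(sim_config(iiv_signal = c(nonsense = 1)), "label")
  expect_error(sim_config(fixed_effects = c(not_a_term = 1)), "unknown")
})
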