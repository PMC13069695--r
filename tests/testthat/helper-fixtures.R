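# Shared fixtures: small configs and generated tables used across tests.

# a generator config with every systematic effect switched off except the
# intercept: marginal NB2(mu = exp(b0), theta) counts
flat_config <- function(b0 = log(2), theta = 1e9, n = 500, waves = 8,
                        seed = 42, cap = 100L, sigma_p = 0,
                        extra = list()) {
  zero_fe <- default_fixed_effects() * 0
  zero_fe["intercept"] <- b0
  args <- list(n_participants = n, n_waves = waves,
               dropout_prob = 0, reentry_prob = 1, entry_wave1_frac = 1,
               fixed_effects = zero_fe, theta = theta,
               sigma_participant = sigma_p, sigma_district = 0,
               seasonal_amplitude = 0, stringency_effect = 0,
               count_cap = cap, seed = seed,
               missing_probs = list(sex = 0, pre_health = 0,
                                    quarantine = 0, risk_perception = 0),
               infection_missing_early = 0, infection_missing_late = 0)
  do.call(sim_config, utils::modifyList(args, extra))
}

# lean model specification matching the generator's systematic structure
lean_model_spec <- function(re = c("participant", "district")) {
  model_spec(fixed_terms = c("age_group", "sex", "household_size",
                             "occupation", "weekday"),
             spline_terms = c(day_of_year = 3L, SI = 3L),
             random_intercepts = re)
}

# dense-integration oracle for the single-RE marginal log-likelihood:
# trapezoid rule on a wide, fine grid per group, in log space
dense_marginal_loglik <- function(design, beta, theta, sigma,
                                  half_width = 8, n_grid = 4001) {
  eta0 <- as.numeric(design$X %*% beta)
  g <- design$re[[1L]]
  b_grid <- seq(-half_width * sigma, half_width * sigma,
                length.out = n_grid)
  h <- b_grid[2] - b_grid[1]
  total <- 0
  for (lev in levels(g)) {
    i <- which(g == lev)
    lp <- vapply(b_grid, function(b)
      sum(dnbinom(design$y[i], size = theta, mu = exp(eta0[i] + b),
                  log = TRUE)) + dnorm(b, 0, sigma, log = TRUE),
      numeric(1))
    m <- max(lp)
    total <- total + m + log(sum(exp(lp - m)) * h)
  }
  total
}

# small single-random-effect fixture for likelihood checks
make_small_fit_data <- function(n = 20, waves = 6, seed = 55) {
  cfg <- flat_config(b0 = 0.6, theta = 1.5, n = n, waves = waves,
                     seed = seed, sigma_p = 0.7)
  tab <- simulate_population(cfg)
  spec <- model_spec(fixed_terms = "sex", spline_terms = NULL,
                     random_intercepts = "participant", backend = "agq")
  build_design(spec, tab)
}

# tiny hand-built observation skeleton for window tests (only the columns
# the window operations read)
window_toy <- function(participant_id, days_since_first_dose = NA_real_,
                       SI = 50, report_day = seq_along(participant_id)) {
  data.frame(participant_id = participant_id,
             days_since_first_dose = days_since_first_dose,
             SI = SI,
             report_date = as.Date("2020-04-01") + report_day,
             wave_index = seq_along(participant_id),
             infection_status = factor(NA_character_,
               levels = c("negative", "positive", "not_tested", "waiting")),
             stringsAsFactors = FALSE)
}
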