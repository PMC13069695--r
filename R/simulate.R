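#' Simulate a longitudinal contact-survey panel
#'
#' Draws a long-format table of participant-observations with the
#' structure the two-step IIV analysis assumes: zero-heavy NB2 contact
#' counts capped at `count_cap`, wave-based panel membership with
#' dropout and re-entry, sociodemographic covariates, a district
#' stringency trajectory crossing the 50 threshold, a vaccination
#' rollout, and (optionally) a window-labelled lognormal dispersion
#' signal that inflates within-person variability without moving the
#' mean (`E[u] = 1`).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`. The output is
#'   bit-reproducible given the seed, and the caller's RNG state is
#'   left untouched.
#' @param keep_truth if `TRUE`, append the latent generative quantities
#'   `true_eta`, `true_mu` (conditional mean before inflation) and
#'   `true_s` (the observation's signal log-SD). These columns are for
#'   oracles and diagnostics; [write_survey_csv()] drops them.
#'
#' @return A `data.frame`, one row per retained participant-observation,
#'   with columns `participant_id`, `wave_index`, `report_date`,
#'   `contact_date`, `weekday`, `day_of_year`, `district_id`, `y`,
#'   `age_group`, `sex`, `household_size`, `occupation`,
#'   `vaccination_status`, `first_dose_date`, `days_since_first_dose`,
#'   `pre_health`, `quarantine`, `risk_perception`, `infection_status`,
#'   `n_waves_joined`, `SI`, `trend`, `mortality`.
#' @export
simulate_population <- function(config, seed = config$seed,
                                keep_truth = FALSE) {
  validate_sim_config(config)
  withr::with_seed(as.integer(seed), simulate_population_impl(config, keep_truth))
}

simulate_population_impl <- function(cfg, keep_truth) {
  np <- cfg$n_participants
  nw <- cfg$n_waves
  fe <- cfg$fixed_effects

  # panel membership: staggered recruitment (a share joins at wave 1,
  # the rest at a uniform later wave, keeping wave sizes roughly stable
  # as the survey's panel replenishment did), then a two-state
  # dropout/re-entry chain from each participant's entry wave
  entry <- rep(1L, np)
  if (nw > 1L && cfg$entry_wave1_frac < 1) {
    late <- stats::runif(np) >= cfg$entry_wave1_frac
    entry[late] <- sample(2:nw, sum(late), replace = TRUE)
  }
  active <- matrix(FALSE, np, nw)
  active[cbind(seq_len(np), entry)] <- TRUE
  if (nw > 1L) for (w in 2:nw) {
    u <- stats::runif(np)
    joined <- entry < w
    active[joined, w] <- ifelse(active[joined, w - 1L],
                                u[joined] > cfg$dropout_prob,
                                u[joined] < cfg$reentry_prob)
    active[entry == w, w] <- TRUE
  }

  # participant-level attributes
  age_group <- sample(levels_age(), np, replace = TRUE,
                      prob = c(0.12, 0.38, 0.30, 0.20))
  sex <- sample(levels_sex(), np, replace = TRUE, prob = c(0.5, 0.5))
  household_size <- sample(levels_hh(), np, replace = TRUE,
                           prob = c(0.30, 0.35, 0.35))
  occupation <- vapply(age_group, function(a) {
    switch(a,
      "0-17" = "student",
      "65+" = sample(c("retired", "employed", "homemaker"), 1L,
                     prob = c(0.85, 0.10, 0.05)),
      sample(c("employed", "homemaker", "student", "unemployed", "retired"),
             1L, prob = c(0.72, 0.07, 0.08, 0.09, 0.04)))
  }, character(1))
  pre_health <- sample(c("yes", "no"), np, replace = TRUE, prob = c(0.33, 0.67))
  district_id <- sample.int(cfg$n_districts, np, replace = TRUE)

  # district-level context parameters; stringency phases vary by
  # district so neither regime is systematically over-sampled by the
  # truncation of the panel at the study end
  si_offset <- stats::rnorm(cfg$n_districts, 0, 3)
  si_phase <- stats::runif(cfg$n_districts, 0, 180)
  trend_phase <- stats::runif(cfg$n_districts, 0, 2 * pi)
  b_district <- stats::rnorm(cfg$n_districts, 0, cfg$sigma_district)
  b_participant <- stats::rnorm(np, 0, cfg$sigma_participant)

  # calendar
  wave_stride <- cfg$wave_duration_days + cfg$inter_wave_gap_days
  wave_start <- (seq_len(nw) - 1L) * wave_stride
  study_end_day <- wave_start[nw] + cfg$wave_duration_days - 1L

  # first-dose dates (participant level); NA = never vaccinated in-study
  vaccinated <- stats::runif(np) < cfg$vaccination_uptake
  dose1_day <- rep(NA_real_, np)
  dose1_day[vaccinated] <- cfg$vaccination_rollout_start_day +
    round(stats::rgamma(sum(vaccinated), shape = 1.8, scale = 80))
  dose1_day[!is.na(dose1_day) & dose1_day > study_end_day] <- NA_real_
  dose2_day <- dose1_day + 42
  dose3_day <- dose1_day + 270

  # long format: one row per active participant-wave
  idx <- which(active, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  pid <- idx[, 1L]
  wave <- idx[, 2L]
  n <- length(pid)

  report_day <- wave_start[wave] +
    sample.int(cfg$wave_duration_days, n, replace = TRUE) - 1L
  report_date <- cfg$origin + report_day
  contact_date <- report_date - 1L
  wd_idx <- as.integer(format(contact_date, "%u"))
  weekday <- levels_weekday()[wd_idx]
  day_of_year <- as.POSIXlt(contact_date)$yday + 1L

  d <- district_id[pid]
  SI <- 50 + 14 * cos(2 * pi * (report_day - si_phase[d]) / 180) +
    si_offset[d]
  SI <- pmin(pmax(SI, 0.5), 75)
  trend <- 50 * sin(2 * pi * report_day / 150 + trend_phase[d]) +
    stats::rnorm(n, 0, 5)
  trend <- pmin(pmax(trend, -89.8), 89.6)
  mortality <- pmax(0.2, 4 * exp(-report_day / 400) + stats::rnorm(n, 0, 0.2))

  # vaccination variables per observation
  d1 <- dose1_day[pid]
  days_since_first_dose <- ifelse(is.na(d1), NA_real_, report_day - d1)
  vaccination_status <- rep("0", n)
  vaccination_status[report_day < cfg$vaccination_rollout_start_day] <-
    "not_available"
  doses <- (!is.na(d1) & report_day >= d1) +
    (!is.na(d1) & report_day >= dose2_day[pid]) +
    (!is.na(d1) & report_day >= dose3_day[pid])
  post_rollout <- report_day >= cfg$vaccination_rollout_start_day
  vaccination_status[post_rollout & doses == 1L] <- "1"
  vaccination_status[post_rollout & doses == 2L] <- "2"
  vaccination_status[post_rollout & doses >= 3L] <- "3+"

  # fatigue covariate: waves joined so far (including the current one)
  cum_joined <- t(apply(active, 1L, cumsum))
  n_waves_joined <- cum_joined[cbind(pid, wave)]

  # generative linear predictor
  eta <- fe[["intercept"]] +
    fe[["age_0_17"]] * (age_group[pid] == "0-17") +
    fe[["age_45_64"]] * (age_group[pid] == "45-64") +
    fe[["age_65p"]] * (age_group[pid] == "65+") +
    fe[["sex_female"]] * (sex[pid] == "female") +
    fe[["hh_2"]] * (household_size[pid] == "2") +
    fe[["hh_3p"]] * (household_size[pid] == "3+") +
    fe[["occ_retired"]] * (occupation[pid] == "retired") +
    fe[["occ_homemaker"]] * (occupation[pid] == "homemaker") +
    fe[["occ_student"]] * (occupation[pid] == "student") +
    fe[["occ_unemployed"]] * (occupation[pid] == "unemployed") +
    fe[["weekday_sat"]] * (weekday == "Sat") +
    fe[["weekday_sun"]] * (weekday == "Sun") +
    fe[["vax_dose1"]] * (vaccination_status == "1") +
    fe[["vax_dose2"]] * (vaccination_status == "2") +
    fe[["vax_dose3"]] * (vaccination_status == "3+") +
    cfg$seasonal_amplitude * sin(2 * pi * day_of_year / 366) +
    cfg$stringency_effect * (SI - 50) +
    b_participant[pid] + b_district[d]
  mu <- exp(eta)

  # window-labelled dispersion signal (mean-preserving lognormal factor)
  s_obs <- signal_log_sd(cfg$iiv_signal, SI, days_since_first_dose)
  u <- rep(1, n)
  has_s <- s_obs > 0
  if (any(has_s))
    u[has_s] <- exp(stats::rnorm(sum(has_s)) * s_obs[has_s] -
                      s_obs[has_s]^2 / 2)

  y <- pmin(stats::rnbinom(n, mu = mu * u, size = cfg$theta), cfg$count_cap)

  # observation-level categoricals with configured missingness
  quarantine <- sample(c("yes", "no"), n, replace = TRUE, prob = c(0.03, 0.97))
  risk_perception <- sample(levels_risk(), n, replace = TRUE,
                            prob = c(0.51, 0.24, 0.25))
  infection_status <- sample(levels_infection(), n, replace = TRUE,
                             prob = c(0.25, 0.03, 0.68, 0.04))
  mp <- cfg$missing_probs
  sex_obs <- sex[pid]
  sex_missing <- stats::runif(np) < (mp$sex %||% 0)
  sex_obs[sex_missing[pid]] <- NA_character_
  pre_health_obs <- pre_health[pid]
  ph_missing <- stats::runif(np) < (mp$pre_health %||% 0)
  pre_health_obs[ph_missing[pid]] <- NA_character_
  quarantine[stats::runif(n) < (mp$quarantine %||% 0)] <- NA_character_
  risk_perception[stats::runif(n) < (mp$risk_perception %||% 0)] <-
    NA_character_
  p_inf_miss <- ifelse(wave <= cfg$infection_missing_wave_cut,
                       cfg$infection_missing_early,
                       cfg$infection_missing_late)
  infection_status[stats::runif(n) < p_inf_miss] <- NA_character_

  out <- data.frame(
    participant_id = pid,
    wave_index = wave,
    report_date = report_date,
    contact_date = contact_date,
    weekday = factor(weekday, levels = levels_weekday()),
    day_of_year = day_of_year,
    district_id = d,
    y = as.integer(y),
    age_group = factor(age_group[pid], levels = levels_age()),
    sex = factor(sex_obs, levels = levels_sex()),
    household_size = factor(household_size[pid], levels = levels_hh()),
    occupation = factor(occupation[pid], levels = levels_occupation()),
    vaccination_status = factor(vaccination_status, levels = levels_vax()),
    first_dose_date = cfg$origin + d1,
    days_since_first_dose = days_since_first_dose,
    pre_health = factor(pre_health_obs, levels = c("yes", "no")),
    quarantine = factor(quarantine, levels = c("yes", "no")),
    risk_perception = factor(risk_perception, levels = levels_risk()),
    infection_status = factor(infection_status, levels = levels_infection()),
    n_waves_joined = as.integer(n_waves_joined),
    SI = SI,
    trend = trend,
    mortality = mortality,
    stringsAsFactors = FALSE
  )
  if (keep_truth) {
    out$true_eta <- eta
    out$true_mu <- mu
    out$true_s <- s_obs
  }
  rownames(out) <- NULL
  out
}

# log-SD of the lognormal inflation factor for each observation, from the
# window labels it falls under; independent labelled factors multiply, so
# their log-SDs combine in quadrature
signal_log_sd <- function(iiv_signal, SI, days_since_first_dose,
                          pre_range = c(-100, 0), post_range = c(1, 100)) {
  n <- length(SI)
  if (!length(iiv_signal)) return(numeric(n))
  s2 <- numeric(n)
  g <- function(lab) if (lab %in% names(iiv_signal)) iiv_signal[[lab]] else 0
  s2 <- s2 + ifelse(SI >= 50, g("strong_SI"), g("weak_SI"))^2
  dd <- days_since_first_dose
  in_pre <- !is.na(dd) & dd >= pre_range[1] & dd <= pre_range[2]
  in_post <- !is.na(dd) & dd >= post_range[1] & dd <= post_range[2]
  s2 <- s2 + ifelse(in_pre, g("pre_vax"), 0)^2
  s2 <- s2 + ifelse(in_post, g("post_vax"), 0)^2
  sqrt(s2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

levels_age <- function() c("0-17", "18-44", "45-64", "65+")
levels_sex <- function() c("male", "female")
levels_hh <- function() c("1", "2", "3+")
levels_occupation <- function()
  c("employed", "retired", "homemaker", "student", "unemployed")
levels_vax <- function() c("not_available", "0", "1", "2", "3+")
levels_risk <- function() c("high", "neutral", "low")
levels_infection <- function() c("negative", "positive", "not_tested", "waiting")
levels_weekday <- function() c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
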