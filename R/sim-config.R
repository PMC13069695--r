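#' Configuration for the synthetic contact-survey generator
#'
#' Bundles every parameter of [simulate_population()]: panel mechanics
#' (waves, dropout and re-entry), the fixed-effect coefficients of the
#' generative negative-binomial model, random-intercept standard
#' deviations, temporal and policy effects, the injectable
#' window-labelled dispersion signal, vaccination rollout and the
#' contact-count cap.
#'
#' The generative model mirrors the analysis model: for each retained
#' participant-wave, `y ~ NB2(mu * u, theta)` with
#' `log mu = beta0 + beta'x + seasonal + stringency + b_participant +
#' b_district`, where `u` is an observation-level lognormal inflation
#' factor with log-SD taken from `iiv_signal` by the observation's
#' window label (`u = 1` where the label carries no signal). Counts are
#' capped at `count_cap`.
#'
#' Defaults describe a desk-scale panel: 300 participants over 12 waves
#' of 8 days separated by 11-day gaps, starting 2020-04-01, with
#' dropout probability 0.12 and re-entry probability 0.45 per wave
#' (mean ~9 observations per panel member), mean contact
#' count near 2, dispersion `theta = 1.5` and participant-intercept SD
#' 0.8. The district stringency index follows
#' `50 + 14 cos(2 pi (t - phase_d) / 180)` plus a district offset:
#' lockdown-grade and relaxed phases alternate on a roughly half-year
#' rhythm, crossing the 50 threshold in both directions within the
#' panel, with district-specific timing.
#'
#' @param n_participants number of panel members.
#' @param n_waves number of survey waves (>= 2 for any riSD downstream).
#' @param wave_duration_days,inter_wave_gap_days wave length and gap, days.
#' @param dropout_prob,reentry_prob per-wave transition probabilities of
#'   the participation process (active participants drop out with
#'   `dropout_prob`; inactive ones return with `reentry_prob`).
#' @param entry_wave1_frac share of participants recruited at wave 1;
#'   the remainder enters at a uniformly chosen later wave, emulating
#'   panel replenishment (set to 1 for a closed cohort).
#' @param fixed_effects named numeric vector of generative log-scale
#'   coefficients; unspecified names keep their defaults. See
#'   [default_fixed_effects()] for the full name set.
#' @param theta NB2 dispersion (> 0); conditional variance is
#'   `mu + mu^2 / theta`.
#' @param sigma_participant,sigma_district random-intercept SDs (>= 0).
#' @param seasonal_amplitude amplitude of the `sin(2 pi yd / 366)`
#'   day-of-year term on the log scale.
#' @param stringency_effect slope of the log mean per stringency-index
#'   unit (centred at SI = 50).
#' @param iiv_signal named numeric vector of log-SDs `s_w >= 0` of the
#'   lognormal mean-inflation factor, keyed by window label from
#'   `c("weak_SI", "strong_SI", "pre_vax", "post_vax")`. Empty (default)
#'   means no injected signal. Labels applying jointly combine as the
#'   root of summed squared log-SDs.
#' @param vaccination_rollout_start_day first day (since `origin`) on
#'   which first doses occur; default 269 = 2020-12-26.
#' @param vaccination_uptake fraction of participants that ever receives
#'   a first dose.
#' @param count_cap upper truncation of reported contacts.
#' @param n_districts number of districts.
#' @param missing_probs named list of per-field missingness
#'   probabilities for `sex`, `pre_health`, `quarantine`,
#'   `risk_perception` (per-observation Bernoulli).
#' @param infection_missing_wave_cut waves `<=` this index use
#'   `infection_missing_early` as the infection-status missingness
#'   probability; later waves use `infection_missing_late`.
#' @param infection_missing_early,infection_missing_late infection-status
#'   missingness probabilities before/after the cut.
#' @param origin calendar origin of day 0 (`Date`).
#' @param seed integer RNG seed; the generator is bit-reproducible given
#'   the seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_population()], [oracle_risd_ratio()]
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 50, n_waves = 6, seed = 1)
#' tab <- simulate_population(cfg)
#' range(tab$y)
sim_config <- function(n_participants = 300,
                       n_waves = 12,
                       wave_duration_days = 8,
                       inter_wave_gap_days = 11,
                       dropout_prob = 0.12,
                       reentry_prob = 0.45,
                       entry_wave1_frac = 0.7,
                       fixed_effects = NULL,
                       theta = 1.5,
                       sigma_participant = 0.8,
                       sigma_district = 0.15,
                       seasonal_amplitude = 0.2,
                       stringency_effect = -0.012,
                       iiv_signal = numeric(0),
                       vaccination_rollout_start_day = 269L,
                       vaccination_uptake = 0.75,
                       count_cap = 100L,
                       n_districts = 20L,
                       missing_probs = list(sex = 0.004, pre_health = 0.078,
                                            quarantine = 0.018,
                                            risk_perception = 0.073),
                       infection_missing_wave_cut = 5L,
                       infection_missing_early = 0.863,
                       infection_missing_late = 0.0086,
                       origin = as.Date("2020-04-01"),
                       seed = 1L) {
  fe <- default_fixed_effects()
  if (!is.null(fixed_effects)) {
    if (is.null(names(fixed_effects)) || any(!nzchar(names(fixed_effects))))
      stop("fixed_effects must be a named numeric vector", call. = FALSE)
    unknown <- setdiff(names(fixed_effects), names(fe))
    if (length(unknown))
      stop("unknown fixed_effects name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    fe[names(fixed_effects)] <- fixed_effects
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_waves = as.integer(n_waves),
    wave_duration_days = as.integer(wave_duration_days),
    inter_wave_gap_days = as.integer(inter_wave_gap_days),
    dropout_prob = dropout_prob,
    reentry_prob = reentry_prob,
    entry_wave1_frac = entry_wave1_frac,
    fixed_effects = fe,
    theta = theta,
    sigma_participant = sigma_participant,
    sigma_district = sigma_district,
    seasonal_amplitude = seasonal_amplitude,
    stringency_effect = stringency_effect,
    iiv_signal = iiv_signal,
    vaccination_rollout_start_day = as.integer(vaccination_rollout_start_day),
    vaccination_uptake = vaccination_uptake,
    count_cap = as.integer(count_cap),
    n_districts = as.integer(n_districts),
    missing_probs = missing_probs,
    infection_missing_wave_cut = as.integer(infection_missing_wave_cut),
    infection_missing_early = infection_missing_early,
    infection_missing_late = infection_missing_late,
    origin = as.Date(origin),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default generative fixed effects
#'
#' Named log-scale coefficients of the generator's linear predictor.
#' The intercept 0.4 places the marginal mean contact count near 2 for
#' the default random-effect variances; group contrasts are modest
#' multiplicative effects of the size seen in contact panels (children
#' more variable schedules, fewer weekend work contacts, etc.).
#'
#' @return Named numeric vector.
#' @export
default_fixed_effects <- function() {
  c(intercept = 0.4,
    age_0_17 = 0.2, age_45_64 = -0.1, age_65p = -0.3,
    sex_female = -0.05,
    hh_2 = 0.05, hh_3p = 0.1,
    occ_retired = -0.3, occ_homemaker = -0.2, occ_student = 0.1,
    occ_unemployed = -0.2,
    weekday_sat = -0.25, weekday_sun = -0.35,
    vax_dose1 = 0.1, vax_dose2 = 0.15, vax_dose3 = 0.15)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_participants < 1L || cfg$n_waves < 1L)
    stop("n_participants and n_waves must be positive", call. = FALSE)
  if (!is.finite(cfg$theta) || cfg$theta <= 0)
    stop("theta must be > 0", call. = FALSE)
  sds <- c(sigma_participant = cfg$sigma_participant,
           sigma_district = cfg$sigma_district)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("random-intercept SDs must be >= 0", call. = FALSE)
  pr <- c(cfg$dropout_prob, cfg$reentry_prob, cfg$entry_wave1_frac,
          cfg$vaccination_uptake,
          cfg$infection_missing_early, cfg$infection_missing_late,
          unlist(cfg$missing_probs))
  if (any(pr < 0 | pr > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (length(cfg$iiv_signal)) {
    if (is.null(names(cfg$iiv_signal)))
      stop("iiv_signal must be named by window label", call. = FALSE)
    bad <- setdiff(names(cfg$iiv_signal),
                   c("weak_SI", "strong_SI", "pre_vax", "post_vax"))
    if (length(bad))
      stop("unknown iiv_signal label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(cfg$iiv_signal < 0))
      stop("iiv_signal log-SDs must be >= 0", call. = FALSE)
  }
  if (cfg$count_cap < 1L) stop("count_cap must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  panel: %d participants x %d waves (%d-day waves, %d-day gaps)\n",
              x$n_participants, x$n_waves, x$wave_duration_days,
              x$inter_wave_gap_days))
  cat(sprintf("  dropout %.2f / re-entry %.2f per wave; %d districts\n",
              x$dropout_prob, x$reentry_prob, x$n_districts))
  cat(sprintf("  NB2 theta = %.3g; SDs: participant %.2f, district %.2f\n",
              x$theta, x$sigma_participant, x$sigma_district))
  if (length(x$iiv_signal))
    cat("  iiv_signal:",
        paste(sprintf("%s=%.2f", names(x$iiv_signal), x$iiv_signal),
              collapse = ", "), "\n")
  else cat("  iiv_signal: none\n")
  cat(sprintf("  origin %s, rollout day %d, cap %d, seed %d\n",
              format(x$origin), x$vaccination_rollout_start_day,
              x$count_cap, x$seed))
  invisible(x)
}
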