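#' Paired window specification
#'
#' Defines the within-person paired designs: day-offset windows around
#' the first vaccine dose, or strong/weak policy-stringency periods
#' split at a stringency-index threshold. Boundary conventions follow
#' the interval notation of the designs: offset 0 (the dose date)
#' belongs to the pre-vaccination window, and SI exactly at the
#' threshold counts as strong stringency.
#'
#' @param kind `"vaccination"` or `"stringency"`.
#' @param pre_range,post_range integer day-offset intervals
#'   `c(lo, hi)` relative to the first dose; defaults `[-100, 0]` and
#'   `[1, 100]`.
#' @param si_threshold stringency split point (default 50).
#' @param min_obs_per_side minimum observations required in each window
#'   for a participant to be eligible (>= 2, since each side needs an
#'   SD).
#' @param max_reporting_interval_days optional cap on consecutive
#'   inter-observation gaps (see [apply_sensitivity_filters()]).
#' @param wave_cut_for_recode wave index up to which missing infection
#'   status is recoded as not tested.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(kind = c("vaccination", "stringency"),
                        pre_range = c(-100L, 0L),
                        post_range = c(1L, 100L),
                        si_threshold = 50,
                        min_obs_per_side = 2L,
                        max_reporting_interval_days = NULL,
                        wave_cut_for_recode = 13L) {
  kind <- match.arg(kind)
  if (length(pre_range) != 2L || length(post_range) != 2L ||
      pre_range[1L] > pre_range[2L] || post_range[1L] > post_range[2L])
    stop("pre_range and post_range must be ordered pairs", call. = FALSE)
  if (pre_range[2L] >= post_range[1L])
    stop("pre_range must end before post_range starts", call. = FALSE)
  if (min_obs_per_side < 2L)
    stop("min_obs_per_side must be >= 2", call. = FALSE)
  structure(list(kind = kind, pre_range = pre_range,
                 post_range = post_range, si_threshold = si_threshold,
                 min_obs_per_side = min_obs_per_side,
                 max_reporting_interval_days = max_reporting_interval_days,
                 wave_cut_for_recode = as.integer(wave_cut_for_recode)),
            class = "window_spec")
}

#' Label observations by pre/post first-vaccination window
#'
#' Observations of vaccinated participants are labelled `pre_vax` when
#' their day offset from the first dose falls in `spec$pre_range`
#' (offset 0, the dose date, is pre) and `post_vax` when in
#' `spec$post_range`; offsets outside both windows, and all
#' observations of never-vaccinated participants, are dropped. A
#' participant is eligible when both windows hold at least
#' `spec$min_obs_per_side` observations.
#'
#' @param table observation table with `days_since_first_dose`.
#' @param spec a `window_spec` of kind `"vaccination"`.
#' @return List: `observations` (in-window rows with `window_label`),
#'   `eligible` (participant ids), `counts` (named exclusion
#'   accounting).
#' @export
vaccination_windows <- function(table, spec = window_spec("vaccination")) {
  stopifnot(inherits(spec, "window_spec"))
  if (spec$kind != "vaccination")
    stop("spec must have kind 'vaccination'", call. = FALSE)
  dd <- table$days_since_first_dose
  lab <- rep(NA_character_, nrow(table))
  lab[!is.na(dd) & dd >= spec$pre_range[1L] & dd <= spec$pre_range[2L]] <-
    "pre_vax"
  lab[!is.na(dd) & dd >= spec$post_range[1L] & dd <= spec$post_range[2L]] <-
    "post_vax"
  finish_windows(table, lab, c("pre_vax", "post_vax"), spec,
                 n_never_vaccinated = length(unique(
                   table$participant_id[is.na(dd)])))
}

#' Label observations by strong/weak policy stringency
#'
#' `strong_SI` when the observation's stringency index is at or above
#' `spec$si_threshold`, `weak_SI` below it. Every observation gets a
#' label; eligibility requires `spec$min_obs_per_side` observations
#' under each.
#'
#' @param table observation table with `SI`.
#' @param spec a `window_spec` of kind `"stringency"`.
#' @return As [vaccination_windows()].
#' @export
stringency_windows <- function(table, spec = window_spec("stringency")) {
  stopifnot(inherits(spec, "window_spec"))
  if (spec$kind != "stringency")
    stop("spec must have kind 'stringency'", call. = FALSE)
  lab <- ifelse(table$SI >= spec$si_threshold, "strong_SI", "weak_SI")
  finish_windows(table, lab, c("strong_SI", "weak_SI"), spec,
                 n_never_vaccinated = NA_integer_)
}

finish_windows <- function(table, lab, levels_lab, spec,
                           n_never_vaccinated) {
  keep <- !is.na(lab)
  obs <- table[keep, , drop = FALSE]
  obs$window_label <- factor(lab[keep], levels = levels_lab)
  counts_by <- table(obs$participant_id, obs$window_label)
  ok <- rowSums(counts_by >= spec$min_obs_per_side) == 2L
  eligible <- as.integer(rownames(counts_by)[ok])
  n_total <- length(unique(table$participant_id))
  list(observations = obs,
       eligible = eligible,
       counts = c(participants_in = n_total,
                  participants_never_vaccinated = n_never_vaccinated,
                  participants_no_window_obs =
                    n_total - nrow(counts_by) -
                    ifelse(is.na(n_never_vaccinated), 0L,
                           n_never_vaccinated),
                  participants_below_min_obs = sum(!ok),
                  participants_eligible = length(eligible),
                  obs_in = nrow(table),
                  obs_out_of_window = sum(!keep),
                  obs_labelled = nrow(obs)))
}

#' Recode early-wave missing infection status as not tested
#'
#' In early waves testing access was limited and infection status was
#' predominantly missing; those missings are recoded as `not_tested`.
#' Later waves are left untouched (remaining missing values fall to the
#' complete-case rule downstream).
#'
#' @param table observation table.
#' @param wave_cut last wave index to which the recode applies.
#' @return The table with `infection_status` recoded.
#' @export
recode_infection_status <- function(table, wave_cut = 13L) {
  i <- table$wave_index <= wave_cut & is.na(table$infection_status)
  table$infection_status[i] <- "not_tested"
  table
}

#' Sensitivity filters over riSD inputs
#'
#' Applies the unit filters of the sensitivity suite to an observation
#' table before riSD computation: a minimum number of observations per
#' participant, and a cap on reporting intervals. Under the default
#' `gap_rule = "all_gaps"` a participant is retained only if every
#' consecutive gap between their report dates is at or below
#' `interval_cap` days; `"median_gap"` retains participants whose
#' median gap is within the cap.
#'
#' @param table observation table.
#' @param filters named list from `min_obs` (integer >= 2),
#'   `interval_cap` (days, `Inf` to disable) and `gap_rule`
#'   (`"all_gaps"` or `"median_gap"`). Unknown names are an error.
#' @return Filtered table; attribute `exclusions` counts participants
#'   removed by each filter.
#' @export
apply_sensitivity_filters <- function(table,
                                      filters = list(min_obs = 2L,
                                                     interval_cap = Inf)) {
  known <- c("min_obs", "interval_cap", "gap_rule")
  unknown <- setdiff(names(filters), known)
  if (length(unknown))
    stop("unknown filter name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  min_obs <- filters$min_obs %||% 2L
  cap <- filters$interval_cap %||% Inf
  gap_rule <- filters$gap_rule %||% "all_gaps"
  gap_rule <- match.arg(gap_rule, c("all_gaps", "median_gap"))

  excl <- c(interval_cap = 0L, min_obs = 0L)
  if (is.finite(cap)) {
    bad <- vapply(split(as.numeric(table$report_date),
                        table$participant_id), function(d) {
      if (length(d) < 2L) return(FALSE)
      g <- diff(sort(d))
      if (gap_rule == "all_gaps") any(g > cap) else stats::median(g) > cap
    }, logical(1))
    bad_ids <- as.integer(names(bad)[bad])
    excl["interval_cap"] <- length(bad_ids)
    table <- table[!(table$participant_id %in% bad_ids), , drop = FALSE]
  }
  nn <- table(table$participant_id)
  small <- as.integer(names(nn)[nn < min_obs])
  excl["min_obs"] <- length(small)
  table <- table[!(table$participant_id %in% small), , drop = FALSE]
  attr(table, "exclusions") <- excl
  table
}
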