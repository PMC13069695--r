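#' Brute-force oracle for the between-window riSD ratio
#'
#' Ground truth for signal-recovery checks: simulates replicate panels
#' from the generator, forms Pearson residuals from the TRUE
#' conditional mean and dispersion (no model fitting), computes
#' within-person riSD separately under the two window labels named in
#' `config$iiv_signal`, and returns the ratio of mean riSD
#' (first-named window over second), averaged over replicates with a
#' Monte-Carlo standard error.
#'
#' Per-window means are weighted by the number of observations behind
#' each riSD, matching the estimand of the weighted Gamma window
#' regression the oracle is compared against.
#'
#' @param config a [sim_config()] whose `iiv_signal` names exactly two
#'   window labels from the same design (e.g. `weak_SI` / `strong_SI`).
#' @param n_draws target total number of simulated participants across
#'   replicates; replicates use `config$n_participants` each.
#' @param min_obs minimum observations per person-window side.
#'
#' @return List with `ratio`, `se` (MC standard error over replicates),
#'   `n_reps`, and `per_rep` (the replicate ratios). A warning element
#'   `note` is set when fewer than 4 replicates were possible.
#' @export
oracle_risd_ratio <- function(config, n_draws = 20000L, min_obs = 2L) {
  validate_sim_config(config)
  labs <- names(config$iiv_signal)
  if (length(labs) != 2L)
    stop("config$iiv_signal must name exactly two window labels",
         call. = FALSE)
  n_reps <- max(1L, ceiling(n_draws / config$n_participants))
  ratios <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    tab <- simulate_population(config, seed = config$seed + r - 1L,
                               keep_truth = TRUE)
    rr <- pearson_residuals(tab$y, tab$true_mu, config$theta)
    lab <- oracle_window_label(tab, labs)
    keep <- !is.na(lab)
    rs <- risd(data.frame(participant_id = tab$participant_id[keep],
                          r = rr[keep], window_label = lab[keep]),
               min_obs = min_obs, by = "participant_window")
    m <- vapply(labs, function(l) {
      i <- rs$window_label == l
      stats::weighted.mean(rs$risd[i], rs$weight[i])
    }, numeric(1))
    ratios[r] <- m[[1L]] / m[[2L]]
  }
  ratios <- ratios[is.finite(ratios)]
  se <- if (length(ratios) > 1L) stats::sd(ratios) / sqrt(length(ratios))
        else NA_real_
  out <- list(ratio = mean(ratios), se = se, n_reps = length(ratios),
              per_rep = ratios)
  if (length(ratios) < 4L)
    out$note <- "fewer than 4 replicates; Monte-Carlo SE unreliable"
  out
}

oracle_window_label <- function(tab, labs) {
  if (all(labs %in% c("weak_SI", "strong_SI"))) {
    ifelse(tab$SI >= 50, "strong_SI", "weak_SI")
  } else if (all(labs %in% c("pre_vax", "post_vax"))) {
    dd <- tab$days_since_first_dose
    ifelse(!is.na(dd) & dd >= -100 & dd <= 0, "pre_vax",
           ifelse(!is.na(dd) & dd >= 1 & dd <= 100, "post_vax",
                  NA_character_))
  } else {
    stop("iiv_signal labels must both come from one window design",
         call. = FALSE)
  }
}
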