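#' Pipeline configuration
#'
#' Collects everything one end-to-end run needs: the data source (a
#' [sim_config()] or an input CSV), the baseline [model_spec()], the
#' two paired [window_spec()]s, the riSD-regression covariates and the
#' riSD-stage options. The default simulated panel uses 24 waves
#' (rather than the generator's 12-wave default) so that the
#' vaccination rollout and both stringency regimes fall inside the
#' study period and all three research questions are answerable.
#'
#' @param sim a [sim_config()]; ignored when `input_csv` is given.
#' @param input_csv optional path to a survey CSV.
#' @param model a [model_spec()].
#' @param vaccination,stringency [window_spec()]s for the two paired
#'   designs.
#' @param regression_covariates covariates of the riSD regressions.
#' @param min_obs minimum observations per riSD unit (per side for the
#'   paired designs).
#' @param recode_wave_cut wave cut of the infection-status recode;
#'   `NA` disables the recode.
#' @param zero_policy zero-riSD handling, see [fit_gamma_glm()].
#' @param out_dir directory for run artifacts; `NULL` writes nothing.
#' @param seed seed governing simulation (overrides `sim$seed`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(n_waves = 24L),
                            input_csv = NULL,
                            model = model_spec(),
                            vaccination = window_spec("vaccination"),
                            stringency = window_spec("stringency"),
                            regression_covariates = c("age_group", "sex",
                                                      "household_size",
                                                      "occupation"),
                            min_obs = 2L,
                            recode_wave_cut = 5L,
                            zero_policy = "exclude",
                            out_dir = NULL,
                            seed = NULL) {
  cfg <- list(sim = sim, input_csv = input_csv, model = model,
              vaccination = vaccination, stringency = stringency,
              regression_covariates = regression_covariates,
              min_obs = as.integer(min_obs),
              recode_wave_cut = recode_wave_cut,
              zero_policy = zero_policy, out_dir = out_dir,
              seed = if (is.null(seed)) sim$seed else as.integer(seed))
  if (!is.null(input_csv) && !file.exists(input_csv))
    stop("input_csv does not exist: ", input_csv, call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the four-step IIV analysis end to end
#'
#' Simulate (or read) the survey table, fit the baseline NB2 mixed
#' model, form Pearson residuals, summarise them into riSD, and fit the
#' three weighted Gamma mean-ratio regressions (sociodemographic,
#' pre/post-vaccination window, strong/weak stringency). Writes run
#' artifacts (fitted-model JSON, residual and riSD CSVs, MR tables,
#' manifest, log) when `config$out_dir` is set. Idempotent given the
#' seed: a rerun produces byte-identical numeric tables.
#'
#' @param config a [pipeline_config()].
#' @return List of class `iiv_run`: `table`, `model`, `icc`,
#'   `residuals`, `risd_table`, `fits` (the three `gamma_mr_fit`s),
#'   `mr_tables`, `exclusions` (stage accounting), `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir))
        writeLines(c(log_lines, paste0("FAILED at stage ", name, ": ",
                                       conditionMessage(e))),
                   file.path(config$out_dir, "log.txt"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  prep <- stage("baseline", prepare_residuals(config, say))
  excl <- prep$exclusions

  # research question 1: sociodemographic differences
  rq1 <- stage("risd_regression", {
    rs <- risd(prep$resid_df, min_obs = config$min_obs,
               by = "participant", carry = config$regression_covariates)
    say("riSD units (all observations): %d kept, %d below min_obs",
        nrow(rs), attr(rs, "exclusions")[["below_min_obs"]])
    list(risd = rs,
         fit = fit_gamma_glm(rs, config$regression_covariates,
                             zero_policy = config$zero_policy))
  })
  excl <- rbind(excl, data.frame(
    stage = "risd_min_obs", n_in = nrow(rq1$risd) +
      attr(rq1$risd, "exclusions")[["below_min_obs"]],
    n_used = nrow(rq1$risd),
    n_excluded = attr(rq1$risd, "exclusions")[["below_min_obs"]]))

  # research questions 2 and 3: paired windows
  rq2 <- stage("vaccination_windows",
               window_mr(prep$resid_df, config, "vaccination", say))
  rq3 <- stage("stringency_windows",
               window_mr(prep$resid_df, config, "stringency", say))

  mr_tables <- list(
    sociodemographic = mean_ratio_table(rq1$fit),
    vaccination = if (is.null(rq2$fit)) NULL else mean_ratio_table(rq2$fit),
    stringency = if (is.null(rq3$fit)) NULL else mean_ratio_table(rq3$fit))

  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   package_version =
                     as.character(utils::packageVersion("contactiiv")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   n_obs_model = prep$model$n_obs,
                   backend = prep$model$backend)

  out <- list(table = prep$table, model = prep$model, icc = prep$icc,
              residuals = prep$resid_df, risd_table = rq1$risd,
              fits = list(sociodemographic = rq1$fit, vaccination = rq2$fit,
                          stringency = rq3$fit),
              windows = list(vaccination = rq2$windows,
                             stringency = rq3$windows),
              mr_tables = mr_tables, exclusions = excl,
              manifest = manifest, log = log_lines)
  class(out) <- "iiv_run"

  if (!is.null(config$out_dir)) write_run_artifacts(out, config)
  out
}

# shared first half of the pipeline: data, baseline fit, residuals, ICC
prepare_residuals <- function(config, say = function(...) invisible()) {
  table <- if (!is.null(config$input_csv)) read_survey_csv(config$input_csv)
           else simulate_population(config$sim, seed = config$seed)
  say("input: %d observations, %d participants", nrow(table),
      length(unique(table$participant_id)))
  if (!is.na(config$recode_wave_cut)) {
    n_before <- sum(is.na(table$infection_status))
    table <- recode_infection_status(table, config$recode_wave_cut)
    say("infection-status recode (waves <= %d): %d -> %d missing",
        config$recode_wave_cut, n_before,
        sum(is.na(table$infection_status)))
  }
  design <- build_design(config$model, table)
  say("complete cases: %d of %d rows retained", length(design$y),
      nrow(table))
  model <- fit_nb_glmm(design)
  say("baseline fit (%s): logLik %.2f, theta %.3f, converged %s",
      model$backend, model$loglik, model$theta_hat, model$converged)
  icc <- adjusted_icc(model)
  say("adjusted ICC: %.3f", icc)

  resid_df <- design$table
  resid_df$r <- pearson_residuals(design$y, model$mu_hat, model$theta_hat)

  excl <- data.frame(
    stage = c("input", "complete_case"),
    n_in = c(nrow(table), nrow(table)),
    n_used = c(nrow(table), length(design$y)),
    n_excluded = c(0L, design$n_dropped))
  list(table = table, design = design, model = model, icc = icc,
       resid_df = resid_df, exclusions = excl)
}

# riSD mean-ratio regression for one paired window design
window_mr <- function(resid_df, config, design_kind, say = function(...) NULL,
                      spec = NULL, filters = NULL) {
  spec <- spec %||% config[[design_kind]]
  spec$min_obs_per_side <- max(2L, config$min_obs)
  win <- if (design_kind == "vaccination") vaccination_windows(resid_df, spec)
         else stringency_windows(resid_df, spec)
  obs <- win$observations
  obs <- obs[obs$participant_id %in% win$eligible, , drop = FALSE]
  n_interval_excluded <- 0L
  if (!is.null(filters)) {
    obs <- apply_sensitivity_filters(obs, filters)
    n_interval_excluded <- attr(obs, "exclusions")[["interval_cap"]]
    # re-impose per-side eligibility after interval filtering
    tb <- table(obs$participant_id, obs$window_label)
    ok <- rowSums(tb >= spec$min_obs_per_side) == 2L
    obs <- obs[obs$participant_id %in%
                 as.integer(rownames(tb)[ok]), , drop = FALSE]
  }
  say("%s design: %d eligible participants (of %d)", design_kind,
      length(unique(obs$participant_id)), win$counts[["participants_in"]])
  if (!nrow(obs))
    return(list(fit = NULL, risd = NULL, windows = win,
                note = "no eligible participants"))
  rs <- risd(obs, min_obs = max(2L, config$min_obs),
             by = "participant_window",
             carry = config$regression_covariates)
  levs <- if (design_kind == "vaccination") c("pre_vax", "post_vax")
          else c("strong_SI", "weak_SI")
  rs$window_label <- factor(rs$window_label, levels = levs)
  fit <- tryCatch(
    fit_gamma_glm(rs, c(config$regression_covariates, "window_label"),
                  zero_policy = config$zero_policy),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(list(fit = NULL, risd = rs, windows = win,
                note = conditionMessage(fit),
                n_interval_excluded = n_interval_excluded))
  list(fit = fit, risd = rs, windows = win, note = NA_character_,
       n_interval_excluded = n_interval_excluded)
}

#' Run the sensitivity suite
#'
#' Re-estimates the paired-window mean ratios over the sensitivity
#' grid: minimum observations per side (2, 3, 4), stringency thresholds
#' (45, 50, 55), vaccination windows (+-40, +-50, +-80, -50/+30,
#' +-100 days) and reporting-interval caps (50, 100, none), plus the
#' non-recoded infection-status variant of both main specifications.
#' The baseline model is fitted once per recode setting; windows never
#' trigger a refit (two-step logic). Infeasible cells are reported as
#' `NA` rows with a reason.
#'
#' @param config a [pipeline_config()].
#' @param min_obs,thresholds,interval_caps grid axes.
#' @param windows list of `c(pre_lo, pre_hi, post_lo, post_hi)` day
#'   offsets.
#' @param include_recode_variant also run the two main cells without
#'   the infection-status recode (requires a second baseline fit).
#' @return `data.frame`, one row per grid cell: design, window or
#'   threshold, `min_obs`, `interval_cap`, `recode`, `mr` (window mean
#'   ratio), `ci_lo`, `ci_hi`, `kappa`, `n_units`,
#'   `n_eligible_participants`, `n_excluded_interval`, `note`.
#' @export
run_sensitivity_suite <- function(config,
                                  min_obs = c(2L, 3L, 4L),
                                  thresholds = c(45, 50, 55),
                                  windows = list(c(-100L, 0L, 1L, 100L),
                                                 c(-40L, 0L, 1L, 40L),
                                                 c(-50L, 0L, 1L, 50L),
                                                 c(-80L, 0L, 1L, 80L),
                                                 c(-50L, 0L, 1L, 30L)),
                                  interval_caps = c(50, 100, Inf),
                                  include_recode_variant = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  prep <- prepare_residuals(config)
  rows <- list()

  cell <- function(prep_used, design_kind, spec, mo, cap, recode_flag,
                   window_txt, threshold) {
    cfg2 <- config
    cfg2$min_obs <- mo
    res <- tryCatch(
      window_mr(prep_used$resid_df, cfg2, design_kind, spec = spec,
                filters = list(min_obs = 2L, interval_cap = cap)),
      error = function(e) list(fit = NULL, note = conditionMessage(e)))
    if (is.null(res$fit)) {
      data.frame(design = design_kind, window = window_txt,
                 threshold = threshold, min_obs = mo, interval_cap = cap,
                 recode = recode_flag, mr = NA_real_, ci_lo = NA_real_,
                 ci_hi = NA_real_, kappa = NA_real_, n_units = 0L,
                 n_eligible_participants = 0L,
                 n_excluded_interval = res$n_interval_excluded %||% NA_integer_,
                 note = res$note %||% "no eligible participants",
                 stringsAsFactors = FALSE)
    } else {
      tab <- res$fit$mean_ratios
      wrow <- tab[grepl("^window_label", tab$term) & !tab$reference, ]
      data.frame(design = design_kind, window = window_txt,
                 threshold = threshold, min_obs = mo, interval_cap = cap,
                 recode = recode_flag, mr = wrow$mr[1L],
                 ci_lo = wrow$ci_lo[1L], ci_hi = wrow$ci_hi[1L],
                 kappa = res$fit$kappa, n_units = res$fit$n_units,
                 n_eligible_participants =
                   length(unique(res$risd$participant_id)),
                 n_excluded_interval = res$n_interval_excluded,
                 note = NA_character_, stringsAsFactors = FALSE)
    }
  }

  for (mo in min_obs) for (cap in interval_caps) {
    for (w in windows) {
      spec <- window_spec("vaccination", pre_range = w[1:2],
                          post_range = w[3:4])
      rows[[length(rows) + 1L]] <-
        cell(prep, "vaccination", spec, mo, cap, TRUE,
             sprintf("%d/%d..%d/%d", w[1], w[2], w[3], w[4]), NA_real_)
    }
    for (th in thresholds) {
      spec <- window_spec("stringency", si_threshold = th)
      rows[[length(rows) + 1L]] <-
        cell(prep, "stringency", spec, mo, cap, TRUE, NA_character_, th)
    }
  }

  if (include_recode_variant) {
    cfg_nr <- config
    cfg_nr$recode_wave_cut <- NA
    prep_nr <- prepare_residuals(cfg_nr)
    rows[[length(rows) + 1L]] <-
      cell(prep_nr, "vaccination", config$vaccination, 2L, Inf, FALSE,
           "-100/0..1/100", NA_real_)
    rows[[length(rows) + 1L]] <-
      cell(prep_nr, "stringency", config$stringency, 2L, Inf, FALSE,
           NA_character_, config$stringency$si_threshold)
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_run_artifacts <- function(run, config) {
  od <- config$out_dir
  m <- run$model
  model_json <- list(beta = as.list(m$beta_hat), theta = m$theta_hat,
                     re_variances = as.list(m$re_variances),
                     loglik = m$loglik, converged = m$converged,
                     n_obs = m$n_obs, n_participants = m$n_participants,
                     adjusted_icc = run$icc)
  jsonlite::write_json(model_json, file.path(od, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  mu_tab <- data.frame(participant_id = run$residuals$participant_id,
                       wave_index = run$residuals$wave_index,
                       mu_hat = m$mu_hat, eta_hat = m$eta_hat)
  utils::write.csv(mu_tab, file.path(od, "mu_hat.csv"), row.names = FALSE)
  utils::write.csv(run$residuals[c("participant_id", "wave_index",
                                   "report_date", "y", "r")],
                   file.path(od, "residuals.csv"), row.names = FALSE)
  utils::write.csv(run$risd_table, file.path(od, "risd.csv"),
                   row.names = FALSE)
  for (nm in names(run$mr_tables))
    if (!is.null(run$mr_tables[[nm]]))
      utils::write.csv(run$mr_tables[[nm]],
                       file.path(od, paste0("mr_", nm, ".csv")),
                       row.names = FALSE)
  utils::write.csv(run$exclusions, file.path(od, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(run$log, file.path(od, "log.txt"))
  invisible(od)
}

# deterministic polynomial hash of the canonical JSON encoding of a
# config; the output directory is not part of the analysis identity
config_hash <- function(config) {
  config$out_dir <- NULL
  txt <- jsonlite::toJSON(unclass(rapply(config, function(x)
    if (inherits(x, "Date")) format(x) else x, how = "replace")),
    auto_unbox = TRUE, digits = NA, force = TRUE, null = "null")
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' @export
print.iiv_run <- function(x, ...) {
  cat("<iiv_run>\n")
  cat(sprintf("  baseline: %d obs, theta %.3f, adjusted ICC %.3f\n",
              x$model$n_obs, x$model$theta_hat, x$icc))
  cat(sprintf("  riSD units: %d (sociodemographic analysis)\n",
              nrow(x$risd_table)))
  for (nm in c("vaccination", "stringency")) {
    f <- x$fits[[nm]]
    if (is.null(f)) { cat(sprintf("  %s: infeasible\n", nm)); next }
    tab <- f$mean_ratios
    wrow <- tab[grepl("^window_label", tab$term) & !tab$reference, ]
    cat(sprintf("  %s window MR: %.3f (%.3f-%.3f), %d units\n", nm,
                wrow$mr[1L], wrow$ci_lo[1L], wrow$ci_hi[1L], f$n_units))
  }
  invisible(x)
}
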