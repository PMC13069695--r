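#' Specification of the baseline contact model
#'
#' Declares which covariates enter the NB2 mixed model's linear
#' predictor, which continuous context variables get natural cubic
#' spline bases, and which random intercepts are included. Reference
#' levels are fixed by the schema: age 18-44, male, household size 1,
#' employed, vaccine not available, no pre-existing condition, no
#' quarantine, high risk perception, negative test, and contact-date
#' weekday Monday.
#'
#' @param fixed_terms character vector of covariate columns entering as
#'   fixed effects (categoricals use treatment contrasts against the
#'   stated references; numerics enter linearly).
#' @param spline_terms named integer vector: variable name (one of
#'   `day_of_year`, `SI`, `trend`, `mortality`) to spline
#'   degrees-of-freedom (>= 3); natural cubic bases with internal knots
#'   at quantiles of the retained data.
#' @param random_intercepts subset of
#'   `c("participant", "report_date", "report_week", "district")`.
#'   `participant` must be present when riSD is computed downstream.
#' @param backend `"glmmTMB"` (Laplace, any random-effect structure) or
#'   `"agq"` (own adaptive Gauss-Hermite fit, exactly one factor).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed_terms = c("age_group", "sex", "household_size",
                                       "occupation", "vaccination_status",
                                       "pre_health", "quarantine",
                                       "risk_perception", "infection_status",
                                       "n_waves_joined", "weekday"),
                       spline_terms = c(day_of_year = 5L, SI = 5L,
                                        trend = 5L, mortality = 5L),
                       random_intercepts = c("participant", "report_date",
                                             "report_week", "district"),
                       backend = c("glmmTMB", "agq")) {
  backend <- match.arg(backend)
  allowed_re <- c("participant", "report_date", "report_week", "district")
  bad <- setdiff(random_intercepts, allowed_re)
  if (length(bad))
    stop("unknown random intercept(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!length(random_intercepts))
    stop("at least one random intercept is required", call. = FALSE)
  if (length(spline_terms)) {
    if (is.null(names(spline_terms)))
      stop("spline_terms must be named", call. = FALSE)
    bad <- setdiff(names(spline_terms),
                   c("day_of_year", "SI", "trend", "mortality"))
    if (length(bad))
      stop("unknown spline variable(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(spline_terms < 3L))
      stop("spline df must be >= 3", call. = FALSE)
  }
  structure(list(fixed_terms = fixed_terms,
                 spline_terms = spline_terms,
                 random_intercepts = random_intercepts,
                 backend = backend),
            class = "model_spec")
}

reference_levels <- function() {
  c(age_group = "18-44", sex = "male", household_size = "1",
    occupation = "employed", vaccination_status = "not_available",
    pre_health = "no", quarantine = "no", risk_perception = "high",
    infection_status = "negative", weekday = "Mon")
}

#' Build the design bundle for the baseline model
#'
#' Applies the complete-case rule over every variable the specification
#' uses, encodes categoricals as treatment contrasts against the schema
#' reference levels, evaluates natural cubic spline bases (knots at
#' quantiles of the retained data), and assembles the random-effect
#' factor index vectors. The reporting-week factor groups report dates
#' into Monday-to-Sunday calendar weeks keyed by the week's Monday.
#'
#' @param spec a [model_spec()].
#' @param table schema-valid observation table.
#' @return List of class `nb_design`: `y`, `X` (fixed-effect matrix with
#'   intercept), `re` (named list of factors), `mask` (logical row
#'   retention over the input), `n_dropped`, `table` (retained rows).
#' @export
build_design <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(table))
  used <- unique(c("y", spec$fixed_terms, names(spec$spline_terms)))
  re_cols <- c(participant = "participant_id", report_date = "report_date",
               report_week = "report_date", district = "district_id")
  used <- unique(c(used, unname(re_cols[spec$random_intercepts])))
  missing_cols <- setdiff(used, names(table))
  if (length(missing_cols))
    stop("table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)

  mask <- !Reduce(`|`, lapply(table[used], is.na))
  dat <- table[mask, , drop = FALSE]
  if (!nrow(dat))
    stop("no complete-case rows remain after exclusions", call. = FALSE)

  refs <- reference_levels()
  for (v in spec$fixed_terms) {
    if (is.factor(dat[[v]]) || is.character(dat[[v]])) {
      f <- droplevels(as.factor(dat[[v]]))
      if (nlevels(f) < 2L)
        stop("factor '", v, "' has a single observed level", call. = FALSE)
      if (v %in% names(refs) && refs[[v]] %in% levels(f))
        f <- stats::relevel(f, ref = refs[[v]])
      dat[[v]] <- f
    }
  }

  terms_txt <- spec$fixed_terms
  spline_bases <- list()
  if (length(spec$spline_terms)) {
    for (v in names(spec$spline_terms)) {
      basis <- splines::ns(dat[[v]], df = spec$spline_terms[[v]])
      colnames(basis) <- paste0("ns_", v, "_", seq_len(ncol(basis)))
      spline_bases[[v]] <- basis
    }
  }

  X <- if (length(terms_txt)) {
    fml <- stats::as.formula(paste("~", paste(terms_txt, collapse = " + ")))
    stats::model.matrix(fml, data = dat)
  } else {
    matrix(1, nrow(dat), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (length(spline_bases)) X <- cbind(X, do.call(cbind, spline_bases))

  re <- list()
  for (f in spec$random_intercepts) {
    re[[f]] <- switch(f,
      participant = factor(dat$participant_id),
      report_date = factor(format(dat$report_date, "%Y-%m-%d")),
      report_week = factor(format(week_monday(dat$report_date), "%Y-%m-%d")),
      district = factor(dat$district_id))
  }

  structure(list(y = dat$y, X = X, re = re, mask = mask,
                 n_dropped = sum(!mask), table = dat, spec = spec),
            class = "nb_design")
}

# Monday of the calendar week containing each date
week_monday <- function(dates) {
  dates - (as.integer(format(dates, "%u")) - 1L)
}
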