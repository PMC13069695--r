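#' Weighted Gamma log-link regression of riSD
#'
#' Models person (or person-window) riSD values as Gamma with log link,
#' each unit's log-likelihood contribution multiplied by its precision
#' weight (the number of observations behind the riSD). Exponentiated
#' coefficients are mean ratios (MR): multiplicative effects on
#' expected riSD. Coefficients come from the weighted score equations
#' (via [stats::glm()]); the shape `kappa` is estimated by the
#' weighted Pearson moment estimator (default; robust to the riSD
#' distribution not being exactly Gamma, which keeps Wald intervals
#' honestly wide) or by maximising the weighted Gamma log-likelihood; Wald 95% intervals use
#' `cov(beta) = (X' W X)^{-1} / kappa`.
#'
#' Zero riSD values (a person whose residuals are constant) have no
#' Gamma likelihood; the default policy excludes them with a recorded
#' count, the alternative shifts them up to half the smallest positive
#' riSD.
#'
#' Weights are relative: doubling all weights never moves the point
#' estimates. Under the default Pearson shape the weight scale cancels
#' entirely (the dispersion estimate absorbs it), so standard errors
#' are also invariant and only ratios of weights carry meaning; under
#' `shape = "ml"` the weights are taken at face value as replication
#' counts and doubling them shrinks standard errors by `sqrt(2)`.
#'
#' @param risd_records output of [risd()] (or any `data.frame` with
#'   `risd`, `weight` and the covariate columns).
#' @param covariates character vector of covariate column names (use
#'   `"window_label"` for the paired designs); interactions may be
#'   written as `"a:b"`. `NULL` fits an intercept-only model.
#' @param weights column name of the precision weights.
#' @param zero_policy `"exclude"` or `"half_min"`.
#' @param shape `"pearson"` (moment) or `"ml"`.
#' @return Object of class `gamma_mr_fit`: `coefficients`, `kappa`,
#'   `vcov`, `mean_ratios` (see [mean_ratio_table()]), `n_units`,
#'   `n_zero_excluded`, `weights_used`, `formula`, `unstable_se`
#'   (levels with a single unit), and the underlying `glm`.
#' @export
fit_gamma_glm <- function(risd_records, covariates = NULL,
                          weights = "weight",
                          zero_policy = c("exclude", "half_min"),
                          shape = c("pearson", "ml")) {
  zero_policy <- match.arg(zero_policy)
  shape <- match.arg(shape)
  stopifnot(is.data.frame(risd_records), "risd" %in% names(risd_records))
  if (!weights %in% names(risd_records))
    stop("weights column '", weights, "' not found", call. = FALSE)

  d <- risd_records
  n_zero <- sum(d$risd <= 0)
  if (n_zero) {
    if (zero_policy == "exclude") {
      d <- d[d$risd > 0, , drop = FALSE]
    } else {
      shift <- min(d$risd[d$risd > 0]) / 2
      d$risd[d$risd <= 0] <- shift
    }
  }
  if (!nrow(d)) stop("no units with positive riSD remain", call. = FALSE)
  if (any(d$risd <= 0))
    stop("non-positive riSD after adjustment in unit(s): ",
         paste(utils::head(which(d$risd <= 0)), collapse = ", "),
         call. = FALSE)

  rhs <- if (is.null(covariates) || !length(covariates)) "1"
         else paste(covariates, collapse = " + ")
  fml <- stats::as.formula(paste("risd ~", rhs))
  w <- d[[weights]]

  base_vars <- unique(unlist(strsplit(covariates %||% character(0), ":",
                                      fixed = TRUE)))
  # treatment contrasts against the schema reference levels
  refs <- reference_levels()
  for (v in intersect(base_vars, names(d))) {
    if ((is.factor(d[[v]]) || is.character(d[[v]])) &&
        v %in% names(refs)) {
      f <- droplevels(as.factor(d[[v]]))
      if (refs[[v]] %in% levels(f))
        d[[v]] <- stats::relevel(f, ref = refs[[v]])
      else d[[v]] <- f
    }
  }

  # separation guard: factor levels represented by a single unit
  unstable <- character(0)
  for (v in intersect(base_vars, names(d))) {
    if (is.factor(d[[v]]) || is.character(d[[v]])) {
      tb <- table(as.character(d[[v]]))
      thin <- names(tb)[tb <= 1L]
      if (length(thin)) unstable <- c(unstable, paste0(v, "=", thin))
    }
  }
  if (length(unstable))
    warning("level(s) with a single unit; standard errors unstable: ",
            paste(unstable, collapse = ", "), call. = FALSE)

  fit <- stats::glm(fml, family = stats::Gamma(link = "log"),
                    data = d, weights = w,
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100L))

  mu <- stats::fitted(fit)
  kappa <- gamma_shape_estimate(d$risd, mu, w, shape,
                                p = length(stats::coef(fit)))
  cov_unscaled <- summary(fit)$cov.unscaled  # (X' W X)^{-1}
  vcov <- cov_unscaled / kappa
  beta <- stats::coef(fit)
  aliased <- is.na(beta)
  if (any(aliased)) {
    warning("aliased (inestimable) coefficient(s) dropped: ",
            paste(names(beta)[aliased], collapse = ", "), call. = FALSE)
    beta <- beta[!aliased]
  }
  se <- sqrt(diag(vcov))[names(beta)]

  out <- list(coefficients = beta, kappa = kappa, vcov = vcov,
              se = se, n_units = nrow(d), n_zero_excluded =
                if (zero_policy == "exclude") n_zero else 0L,
              weights_used = TRUE, formula = deparse(fml),
              covariates = covariates, unstable_se = unstable,
              zero_policy = zero_policy, shape_method = shape,
              converged = fit$converged, glm = fit, data = d)
  class(out) <- "gamma_mr_fit"
  out$mean_ratios <- mean_ratio_table(out)
  out
}

# weighted Gamma shape: ML solves psi(k) - log(k) = mean_w(log(y/mu) - y/mu) + 1
gamma_shape_estimate <- function(y, mu, w, method, p = 1L) {
  if (method == "pearson") {
    disp <- sum(w * (y - mu)^2 / mu^2) / (length(y) - p)
    return(1 / disp)
  }
  rhs <- stats::weighted.mean(log(y / mu) - y / mu, w) + 1
  f <- function(log_k) {
    k <- exp(log_k)
    digamma(k) - log(k) - rhs
  }
  # psi(k) - log(k) is increasing in k from -Inf to 0; rhs <= 0
  lo <- -15; hi <- 25
  if (f(hi) < 0) return(exp(hi))
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)
  exp(root$root)
}

#' Mean-ratio report table
#'
#' One row per model term: the reference level of each factor (MR fixed
#' at 1), and for every non-reference coefficient the mean ratio
#' `exp(beta)` with its 95% Wald interval
#' `exp(beta +- 1.96 se)`.
#'
#' @param fit a `gamma_mr_fit`.
#' @param conf_z normal quantile of the interval (1.96 for 95%).
#' @return `data.frame` with `term`, `mr`, `ci_lo`, `ci_hi`,
#'   `reference` (logical), `se_log`.
#' @export
mean_ratio_table <- function(fit, conf_z = stats::qnorm(0.975)) {
  stopifnot(inherits(fit, "gamma_mr_fit"))
  keep <- names(fit$coefficients) != "(Intercept)"
  beta <- fit$coefficients[keep]
  se <- fit$se[keep]
  rows <- data.frame(term = names(beta), mr = exp(unname(beta)),
                     ci_lo = exp(unname(beta) - conf_z * unname(se)),
                     ci_hi = exp(unname(beta) + conf_z * unname(se)),
                     reference = logical(length(beta)),
                     se_log = unname(se),
                     stringsAsFactors = FALSE)
  # prepend a reference row per factor covariate
  ref_rows <- list()
  for (v in intersect(fit$covariates %||% character(0), names(fit$data))) {
    x <- fit$data[[v]]
    if (is.factor(x))
      ref_rows[[v]] <- data.frame(term = paste0(v, levels(x)[1L]),
                                  mr = 1, ci_lo = NA_real_,
                                  ci_hi = NA_real_, reference = TRUE,
                                  se_log = NA_real_,
                                  stringsAsFactors = FALSE)
  }
  out <- rbind(do.call(rbind, ref_rows), rows)
  rownames(out) <- NULL
  out
}

#' @export
print.gamma_mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<gamma_mr_fit> %s | %d units, kappa %.3g (%s)\n",
              x$formula, x$n_units, x$kappa, x$shape_method))
  if (x$n_zero_excluded)
    cat(sprintf("  %d zero-riSD unit(s) excluded\n", x$n_zero_excluded))
  tab <- x$mean_ratios
  tab$mr <- round(tab$mr, digits)
  tab$ci_lo <- round(tab$ci_lo, digits)
  tab$ci_hi <- round(tab$ci_hi, digits)
  print(tab[, c("term", "mr", "ci_lo", "ci_hi", "reference")],
        row.names = FALSE)
  invisible(x)
}
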