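#' Fit the baseline NB2 mixed model
#'
#' Maximises the marginal likelihood of the negative-binomial (NB2,
#' log link) mixed model over the design produced by [build_design()].
#' The default backend is glmmTMB (Laplace approximation, arbitrary
#' crossed random intercepts); the `"agq"` backend is the package's own
#' adaptive Gauss-Hermite fit, available when the design has exactly
#' one random-effect factor, and exists so the marginal likelihood can
#' be verified against dense numerical integration.
#'
#' Fitted conditional means are empirical-Bayes: `mu = exp(X beta_hat +
#' sum of predicted random-intercept modes)`, the expected contact
#' level the Pearson residuals are taken against.
#'
#' @param design an `nb_design` from [build_design()].
#' @param backend `"glmmTMB"` or `"agq"`; defaults to the spec's.
#' @param nodes Gauss-Hermite nodes for the `"agq"` backend.
#' @param theta_cap upper bound on the dispersion estimate; a fit
#'   pushing above it (effectively Poisson counts) is capped with a
#'   warning rather than left diverging.
#' @return Object of class `nb_glmm_fit` with elements `beta_hat`,
#'   `theta_hat`, `re_variances`, `re_modes`, `mu_hat`, `eta_hat`,
#'   `loglik`, `converged`, `n_obs`, `n_participants`, `se`
#'   (`beta`, `log_theta`, `log_sigma`), `backend`, and the raw
#'   backend `fit`.
#' @export
fit_nb_glmm <- function(design, backend = NULL, nodes = 15L,
                        theta_cap = 1e6) {
  stopifnot(inherits(design, "nb_design"))
  if (is.null(backend)) backend <- design$spec$backend
  backend <- match.arg(backend, c("glmmTMB", "agq"))
  if (any(design$y < 0) || any(design$y != round(design$y)))
    stop("counts must be non-negative integers", call. = FALSE)
  fit <- if (backend == "glmmTMB") fit_nb_glmmtmb(design, theta_cap)
         else fit_nb_agq(design, nodes = nodes, theta_cap = theta_cap)
  fit$n_obs <- length(design$y)
  fit$n_participants <-
    if ("participant" %in% names(design$re))
      nlevels(design$re[["participant"]])
    else NA_integer_
  fit$design <- design
  class(fit) <- "nb_glmm_fit"
  fit
}

fit_nb_glmmtmb <- function(design, theta_cap) {
  X <- design$X
  xn <- paste0("x", seq_len(ncol(X)))
  df <- as.data.frame(X)
  names(df) <- xn
  df$y <- design$y
  gn <- paste0("g_", names(design$re))
  for (i in seq_along(design$re)) df[[gn[i]]] <- design$re[[i]]
  fml <- stats::as.formula(paste(
    "y ~ 0 +", paste(xn, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", gn), collapse = " + ")))
  fit <- suppressWarnings(
    glmmTMB::glmmTMB(fml, data = df, family = glmmTMB::nbinom2()))

  beta <- glmmTMB::fixef(fit)$cond
  names(beta) <- colnames(X)
  vc <- glmmTMB::VarCorr(fit)$cond
  re_var <- vapply(gn, function(g) as.numeric(vc[[g]][1L, 1L]), numeric(1))
  names(re_var) <- names(design$re)
  rf <- glmmTMB::ranef(fit)$cond
  re_modes <- lapply(gn, function(g) stats::setNames(rf[[g]][, 1L],
                                                     rownames(rf[[g]])))
  names(re_modes) <- names(design$re)

  theta_hat <- glmmTMB::sigma(fit)
  capped <- FALSE
  if (!is.finite(theta_hat) || theta_hat > theta_cap) {
    warning("dispersion estimate diverging (counts near-Poisson); ",
            "capped at theta_cap", call. = FALSE)
    theta_hat <- theta_cap
    capped <- TRUE
  }

  eta_hat <- as.numeric(stats::predict(fit, type = "link"))
  mu_hat <- exp(eta_hat)

  pf <- fit$sdr$par.fixed
  pse <- sqrt(pmax(diag(fit$sdr$cov.fixed), 0))
  se_beta <- pse[names(pf) == "beta"]
  names(se_beta) <- colnames(X)
  se_log_theta <- unname(pse[names(pf) == "betad"])  # log(theta) scale
  # log-SD scale SEs of the random intercepts, in formula order
  se_log_sigma <- as.numeric(sqrt(pmax(
    diag(as.matrix(fit$sdr$cov.fixed))[names(pf) == "theta"], 0)))
  names(se_log_sigma) <- names(design$re)

  conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  list(beta_hat = beta, theta_hat = theta_hat, theta_capped = capped,
       re_variances = re_var, re_modes = re_modes,
       mu_hat = mu_hat, eta_hat = eta_hat,
       loglik = as.numeric(stats::logLik(fit)),
       converged = conv, backend = "glmmTMB",
       se = list(beta = se_beta, log_theta = se_log_theta,
                 log_sigma = se_log_sigma),
       fit = fit)
}

#' Point estimates and standard errors from a fitted NB2 mixed model
#'
#' Convenience extractor for recovery checks: fixed effects on the
#' natural (log-mean) scale, and dispersion / random-intercept SDs on
#' the log scale together with their delta-method standard errors.
#'
#' @param model an `nb_glmm_fit`.
#' @return `data.frame` with columns `parameter`, `estimate`, `se`,
#'   `scale` (`"identity"` or `"log"`).
#' @export
nb_glmm_estimates <- function(model) {
  stopifnot(inherits(model, "nb_glmm_fit"))
  sds <- sqrt(model$re_variances)
  data.frame(
    parameter = c(names(model$beta_hat), "theta",
                  paste0("sigma_", names(sds))),
    estimate = c(unname(model$beta_hat), log(model$theta_hat),
                 log(unname(sds))),
    se = c(unname(model$se$beta), model$se$log_theta,
           unname(model$se$log_sigma)),
    scale = c(rep("identity", length(model$beta_hat)),
              rep("log", 1L + length(sds))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.nb_glmm_fit <- function(x, ...) {
  cat(sprintf("<nb_glmm_fit> backend %s: %d obs, %s participants\n",
              x$backend, x$n_obs,
              ifelse(is.na(x$n_participants), "?", x$n_participants)))
  cat(sprintf("  logLik %.3f, theta %.4g, converged: %s\n",
              x$loglik, x$theta_hat, x$converged))
  cat("  random-intercept variances:\n")
  print(round(x$re_variances, 4))
  invisible(x)
}

#' @export
logLik.nb_glmm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta_hat) + 1L +
              length(object$re_variances), class = "logLik")
}

#' @export
coef.nb_glmm_fit <- function(object, ...) object$beta_hat
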