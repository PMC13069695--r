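#' Adjusted intraclass correlation of the baseline model
#'
#' Share of latent-scale variance attributable to the participant
#' intercept:
#' `ICC = sigma2_participant / (sum of random-intercept variances +
#' sigma2_resid)`, where the distribution-specific residual variance of
#' the NB2 log-link model is, under the lognormal approximation,
#' `sigma2_resid = log(1 + 1/mu_bar + 1/theta)` with `mu_bar` the mean
#' fitted conditional mean; the trigamma form
#' `trigamma(1 / (1/mu_bar + 1/theta))` is available as an alternative.
#'
#' @param model an `nb_glmm_fit` with a participant random intercept,
#'   or a list with elements `re_variances` (named, including
#'   `participant`), `theta_hat` and `mu_hat` (or `mu_bar`).
#' @param method residual-variance approximation.
#' @return ICC in `[0, 1]`.
#' @export
#' @examples
#' adjusted_icc(list(re_variances = c(participant = 1),
#'                   theta_hat = 1, mu_bar = 2))  # 1 / (1 + log 2.5)
adjusted_icc <- function(model, method = c("lognormal", "trigamma")) {
  method <- match.arg(method)
  if (!"participant" %in% names(model$re_variances))
    stop("model has no participant random intercept", call. = FALSE)
  mu_bar <- if (!is.null(model$mu_bar)) model$mu_bar
            else mean(model$mu_hat)
  theta <- model$theta_hat
  stopifnot(is.finite(mu_bar), mu_bar > 0, is.finite(theta), theta > 0)
  resid_var <- switch(method,
    lognormal = log1p(1 / mu_bar + 1 / theta),
    trigamma = trigamma(1 / (1 / mu_bar + 1 / theta)))
  v <- model$re_variances
  unname(v[["participant"]] / (sum(v) + resid_var))
}
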