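#' Pearson residuals under the NB2 conditional variance
#'
#' `r = (y - mu) / sqrt(mu + mu^2 / theta)`: the deviation of an
#' observed count from its fitted conditional mean, scaled by the
#' model-implied standard deviation. As `theta -> Inf` this reduces to
#' the Poisson residual `(y - mu) / sqrt(mu)`.
#'
#' @param y observed counts.
#' @param mu_hat fitted conditional means (> 0), same length as `y`.
#' @param theta_hat NB2 dispersion (> 0), scalar.
#' @return Numeric vector of residuals.
#' @export
#' @examples
#' pearson_residuals(5, 2, 1)  # 3 / sqrt(6)
pearson_residuals <- function(y, mu_hat, theta_hat) {
  if (length(y) != length(mu_hat))
    stop("y and mu_hat must have the same length", call. = FALSE)
  if (length(theta_hat) != 1L || !is.finite(theta_hat) || theta_hat <= 0)
    stop("theta_hat must be a positive scalar", call. = FALSE)
  if (any(!is.finite(mu_hat)) || any(mu_hat <= 0))
    stop("mu_hat must be positive and finite", call. = FALSE)
  (y - mu_hat) / sqrt(mu_hat + mu_hat^2 / theta_hat)
}

#' Within-person residual standard deviation (riSD)
#'
#' The sample standard deviation (n - 1 denominator) of a participant's
#' Pearson residuals, optionally computed separately per window label.
#' Groups with fewer than `min_obs` residuals are excluded (riSD needs
#' at least two observations); the number excluded is recorded in the
#' `"exclusions"` attribute of the result. Each retained group carries
#' `weight = n_obs`, the precision weight used by the downstream Gamma
#' regression.
#'
#' @param residuals `data.frame` with columns `participant_id`, `r`
#'   and, when `by = "participant_window"`, `window_label`. Additional
#'   person-constant columns named in `carry` are passed through
#'   (first value per group).
#' @param min_obs minimum group size (default 2).
#' @param by grouping: per participant, or per participant-window.
#' @param carry character vector of covariate columns to carry into the
#'   output (e.g. sociodemographics for the riSD regression).
#' @return `data.frame` with `participant_id`, `window_label`, `n_obs`,
#'   `risd`, `weight` and any carried columns; attribute `exclusions`
#'   holds the count of groups dropped for `n < min_obs`.
#' @export
risd <- function(residuals, min_obs = 2L,
                 by = c("participant", "participant_window"),
                 carry = character(0)) {
  by <- match.arg(by)
  stopifnot(is.data.frame(residuals),
            all(c("participant_id", "r") %in% names(residuals)))
  if (min_obs < 2L) stop("min_obs must be >= 2", call. = FALSE)
  if (by == "participant_window" &&
      !"window_label" %in% names(residuals))
    stop("window_label column required for by = 'participant_window'",
         call. = FALSE)
  missing_carry <- setdiff(carry, names(residuals))
  if (length(missing_carry))
    stop("carry column(s) not present: ",
         paste(missing_carry, collapse = ", "), call. = FALSE)

  key <- if (by == "participant") list(participant_id = residuals$participant_id)
         else list(participant_id = residuals$participant_id,
                   window_label = as.character(residuals$window_label))
  grp <- interaction(key, drop = TRUE, lex.order = TRUE)
  n_obs <- as.integer(tapply(residuals$r, grp, length))
  sds <- as.numeric(tapply(residuals$r, grp, stats::sd))
  first_idx <- match(levels(grp), as.character(grp))

  out <- data.frame(
    participant_id = residuals$participant_id[first_idx],
    window_label = if (by == "participant") "all"
                   else as.character(residuals$window_label)[first_idx],
    n_obs = n_obs,
    risd = sds,
    stringsAsFactors = FALSE
  )
  for (cc in carry) out[[cc]] <- residuals[[cc]][first_idx]
  keep <- out$n_obs >= min_obs
  n_excluded <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  out$weight <- out$n_obs
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(below_min_obs = n_excluded)
  out
}
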