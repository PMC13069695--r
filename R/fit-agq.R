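# Adaptive Gauss-Hermite fit for the single-random-intercept NB2 model.
#
# The marginal likelihood integrates the NB2 likelihood over each
# group's intercept:
#   L_i = integral prod_t NB2(y_it | exp(eta0_it + b), theta) phi(b; 0, s^2) db
# Each integral is centred at the posterior mode b_i (found by damped
# Newton, vectorised across groups) and scaled by the local curvature,
# then evaluated with Gauss-Hermite nodes. This route exists alongside
# the Laplace backend so the optimum can be checked against dense
# numerical integration.

# Gauss-Hermite nodes and weights for weight function exp(-x^2),
# via the Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# posterior modes and curvatures of the group intercepts, by damped Newton
agq_modes <- function(y, eta0, gidx, theta, sigma, n_groups,
                      tol = 1e-10, maxit = 50L) {
  b <- numeric(n_groups)
  for (it in seq_len(maxit)) {
    mu <- exp(eta0 + b[gidx])
    g1 <- y - (y + theta) * mu / (mu + theta)
    h1 <- -(y + theta) * theta * mu / (mu + theta)^2
    grad <- as.numeric(rowsum(g1, gidx)) - b / sigma^2
    hess <- as.numeric(rowsum(h1, gidx)) - 1 / sigma^2
    step <- grad / hess
    step <- pmin(pmax(step, -4), 4)  # damp early wild steps
    b <- b - step
    if (max(abs(grad)) < tol) break
  }
  mu <- exp(eta0 + b[gidx])
  h1 <- -(y + theta) * theta * mu / (mu + theta)^2
  hess <- as.numeric(rowsum(h1, gidx)) - 1 / sigma^2
  list(b = b, curvature = -hess)
}

#' Adaptive Gauss-Hermite marginal log-likelihood
#'
#' Evaluates the exact (to quadrature accuracy) marginal log-likelihood
#' of the single-random-intercept NB2 model at given parameter values.
#' Exposed so the value at an optimum can be compared against an
#' independent dense-integration computation.
#'
#' @param design `nb_design` with exactly one random-effect factor.
#' @param beta fixed-effect vector (length `ncol(design$X)`).
#' @param theta NB2 dispersion (> 0).
#' @param sigma random-intercept SD (> 0).
#' @param nodes number of Gauss-Hermite nodes.
#' @return Scalar log-likelihood.
#' @export
nb_agq_loglik <- function(design, beta, theta, sigma, nodes = 15L) {
  stopifnot(inherits(design, "nb_design"), length(design$re) == 1L)
  gh <- gauss_hermite(nodes)
  agq_loglik_impl(design$y, as.numeric(design$X %*% beta),
                  as.integer(design$re[[1L]]), theta, sigma,
                  nlevels(design$re[[1L]]), gh)
}

agq_loglik_impl <- function(y, eta0, gidx, theta, sigma, n_groups, gh) {
  md <- agq_modes(y, eta0, gidx, theta, sigma, n_groups)
  s <- 1 / sqrt(md$curvature)
  K <- length(gh$nodes)
  ll_nodes <- matrix(0, n_groups, K)
  for (k in seq_len(K)) {
    bk <- md$b + sqrt(2) * s * gh$nodes[k]
    lk <- stats::dnbinom(y, size = theta, mu = exp(eta0 + bk[gidx]),
                         log = TRUE)
    ll_nodes[, k] <- as.numeric(rowsum(lk, gidx)) +
      stats::dnorm(bk, 0, sigma, log = TRUE) + gh$nodes[k]^2 +
      log(gh$weights[k])
  }
  m <- apply(ll_nodes, 1L, max)
  sum(m + log(rowSums(exp(ll_nodes - m))) + log(sqrt(2) * s))
}

fit_nb_agq <- function(design, nodes = 15L, theta_cap = 1e6,
                       maxit = 500L) {
  if (length(design$re) != 1L)
    stop("the 'agq' backend supports exactly one random-effect factor",
         call. = FALSE)
  y <- design$y
  X <- design$X
  gidx <- as.integer(design$re[[1L]])
  n_groups <- nlevels(design$re[[1L]])
  gh <- gauss_hermite(nodes)

  # starting values: Poisson GLM for beta, mild dispersion/SD guesses
  start_fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson()))
  par0 <- c(start_fit$coefficients, log(1), log(0.5))
  p <- ncol(X)

  negll <- function(par) {
    theta <- exp(par[p + 1L])
    sigma <- exp(par[p + 2L])
    if (!is.finite(theta) || !is.finite(sigma) || sigma < 1e-8)
      return(1e10)
    ll <- agq_loglik_impl(y, as.numeric(X %*% par[seq_len(p)]),
                          gidx, theta, sigma, n_groups, gh)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(par0, negll, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12),
                      hessian = TRUE)

  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  theta_hat <- exp(unname(opt$par[p + 1L]))
  capped <- FALSE
  if (theta_hat > theta_cap) {
    warning("dispersion estimate diverging; capped at theta_cap",
            call. = FALSE)
    theta_hat <- theta_cap
    capped <- TRUE
  }
  sigma_hat <- exp(unname(opt$par[p + 2L]))

  md <- agq_modes(y, as.numeric(X %*% beta), gidx, theta_hat, sigma_hat,
                  n_groups)
  b_hat <- stats::setNames(md$b, levels(design$re[[1L]]))
  eta_hat <- as.numeric(X %*% beta) + md$b[gidx]

  cov <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  pse <- if (is.null(cov)) rep(NA_real_, p + 2L)
         else sqrt(pmax(diag(cov), 0))
  se_log_sigma <- stats::setNames(pse[p + 2L], names(design$re))

  list(beta_hat = beta, theta_hat = theta_hat, theta_capped = capped,
       re_variances = stats::setNames(sigma_hat^2, names(design$re)),
       re_modes = stats::setNames(list(b_hat), names(design$re)),
       mu_hat = exp(eta_hat), eta_hat = eta_hat,
       loglik = -opt$value,
       converged = opt$convergence == 0,
       backend = "agq",
       se = list(beta = stats::setNames(pse[seq_len(p)], colnames(X)),
                 log_theta = pse[p + 1L], log_sigma = se_log_sigma),
       fit = opt)
}
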