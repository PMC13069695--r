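test_that("AGQ marginal log-likelihood matches dense integration", {
  des <- make_small_fit_data()
  fit <- fit_nb_glmm(des, backend = "agq", nodes = 25)
  expect_true(fit$converged)
  oracle <- dense_marginal_loglik(des, fit$beta_hat, fit$theta_hat,
                                  sqrt(fit$re_variances[["participant"]]))
  expect_equal(fit$loglik, oracle, tolerance = 1e-4)
  # the exported evaluator agrees at arbitrary (non-optimal) parameters
  beta2 <- fit$beta_hat * 0.8
  ll2 <- nb_agq_loglik(des, beta2, 2, 0.5, nodes = 25)
  expect_equal(ll2, dense_marginal_loglik(des, beta2, 2, 0.5),
               tolerance = 1e-4)
})

test_that("AGQ and glmmTMB agree on the same single-RE design", {
  des <- make_small_fit_data(n = 40, waves = 6, seed = 56)
  f_agq <- fit_nb_glmm(des, backend = "agq", nodes = 21)
  f_tmb <- fit_nb_glmm(des, backend = "glmmTMB")
  expect_equal(unname(f_agq$beta_hat), unname(f_tmb$beta_hat),
               tolerance = 0.02)
  expect_equal(f_agq$theta_hat, f_tmb$theta_hat, tolerance = 0.05)
  # Laplace <= AGQ-corrected likelihood differences stay small here
  expect_equal(f_agq$loglik, f_tmb$loglik, tolerance = 0.5)
})

test_that("zero random-effect variance reduces to a plain NB regression", {
  cfg <- flat_config(b0 = 0.5, theta = 1.5, n = 250, waves = 8, seed = 57,
                     sigma_p = 0)
  tab <- simulate_population(cfg)
  spec <- model_spec(fixed_terms = "sex", spline_terms = NULL,
                     random_intercepts = "participant")
  des <- build_design(spec, tab)
  fit <- suppressWarnings(fit_nb_glmm(des))
  expect_lt(fit$re_variances[["participant"]], 1e-3)
  plain <- MASS::glm.nb(des$y ~ des$X + 0)
  expect_equal(unname(fit$beta_hat), unname(coef(plain)), tolerance = 1e-3)
  expect_equal(fit$theta_hat, plain$theta, tolerance = 0.01)
})

test_that("fitted means honour the log link and residuals centre near zero", {
  cfg <- flat_config(b0 = 0.5, theta = 1.5, n = 150, waves = 8, seed = 58,
                     sigma_p = 0.8)
  tab <- simulate_population(cfg)
  spec <- model_spec(fixed_terms = "sex", spline_terms = NULL,
                     random_intercepts = "participant")
  fit <- fit_nb_glmm(build_design(spec, tab))
  expect_equal(fit$mu_hat, exp(fit$eta_hat), tolerance = 1e-12)
  expect_true(all(is.finite(fit$mu_hat)) && all(fit$mu_hat > 0))
  r <- pearson_residuals(fit$design$y, fit$mu_hat, fit$theta_hat)
  expect_lt(abs(mean(r)), 0.05)
})

test_that("single-seed recovery lands near the generative parameters", {
  cfg <- flat_config(b0 = 0.5, theta = 1.5, n = 400, waves = 8, seed = 59,
                     sigma_p = 0.8,
                     extra = list(fixed_effects = c(intercept = 0.5,
                                                    sex_female = 0.7)))
  tab <- simulate_population(cfg)
  spec <- model_spec(fixed_terms = "sex", spline_terms = NULL,
                     random_intercepts = "participant")
  fit <- fit_nb_glmm(build_design(spec, tab))
  est <- nb_glmm_estimates(fit)
  expect_equal(est$estimate[est$parameter == "sexfemale"], 0.7,
               tolerance = 0.15)
  expect_equal(exp(est$estimate[est$parameter == "theta"]), 1.5,
               tolerance = 0.2)
  expect_equal(exp(est$estimate[est$parameter == "sigma_participant"]),
               0.8, tolerance = 0.15)
  expect_true(all(is.finite(est$se) & est$se > 0))
})

test_that("counts must be non-negative integers and REs declared", {
  des <- make_small_fit_data(n = 10, waves = 4, seed = 60)
  des$y[1] <- -1L
  expect_error(fit_nb_glmm(des), "non-negative")
})
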