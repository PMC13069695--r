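test_that("intercept-only weighted fit is the weighted mean", {
  d <- data.frame(risd = c(1, 2), weight = c(2, 4))
  fit <- fit_gamma_glm(d)
  expect_equal(unname(exp(fit$coefficients)), (2 * 1 + 4 * 2) / 6,
               tolerance = 1e-8)
})

test_that("saturated binary covariate gives the ratio of weighted means", {
  d <- data.frame(risd = c(0.8, 1.2, 1.2, 1.6),
                  weight = c(3, 3, 2, 4),
                  grp = factor(c("a", "a", "b", "b")))
  fit <- fit_gamma_glm(d, "grp")
  m_a <- weighted.mean(c(0.8, 1.2), c(3, 3))
  m_b <- weighted.mean(c(1.2, 1.6), c(2, 4))
  mr <- fit$mean_ratios
  expect_equal(mr$mr[mr$term == "grpb"], m_b / m_a, tolerance = 1e-8)
})

test_that("doubling all weights never moves the point estimates", {
  set.seed(41)
  d <- data.frame(risd = rgamma(200, 2, 2),
                  weight = sample(2:10, 200, TRUE),
                  grp = factor(sample(c("a", "b"), 200, TRUE)))
  d2 <- d; d2$weight <- d2$weight * 2
  # Pearson shape: the dispersion absorbs the scale, SEs invariant
  f1 <- fit_gamma_glm(d, "grp")
  f2 <- fit_gamma_glm(d2, "grp")
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-10)
  expect_equal(f2$kappa, f1$kappa / 2, tolerance = 1e-8)
  expect_equal(f2$se, f1$se, tolerance = 1e-8)
  # ML shape: weights act as replication counts, SEs shrink by sqrt(2)
  g1 <- fit_gamma_glm(d, "grp", shape = "ml")
  g2 <- fit_gamma_glm(d2, "grp", shape = "ml")
  expect_equal(g2$coefficients, g1$coefficients, tolerance = 1e-10)
  expect_equal(g2$kappa, g1$kappa, tolerance = 1e-8)
  expect_equal(g2$se, g1$se / sqrt(2), tolerance = 1e-8)
})

test_that("coefficient ordering equals mean-ratio ordering", {
  set.seed(42)
  d <- data.frame(risd = rgamma(300, 2, 2),
                  weight = sample(2:8, 300, TRUE),
                  grp = factor(sample(letters[1:4], 300, TRUE)))
  fit <- fit_gamma_glm(d, "grp")
  co <- fit$coefficients[-1]
  mrs <- fit$mean_ratios
  mrs <- mrs[!mrs$reference & mrs$term != "(Intercept)", ]
  expect_equal(order(co), order(mrs$mr[match(names(co), mrs$term)]))
  # CI construction is exp(beta +- 1.96 se)
  expect_equal(mrs$ci_hi[mrs$term == names(co)[1]],
               exp(unname(co[1]) +
                     qnorm(0.975) * unname(fit$se[names(co)[1]])),
               tolerance = 1e-10)
})

test_that("zero riSD units follow the stated policy", {
  d <- data.frame(risd = c(0, 0.4, 0.8, 1.2), weight = c(2, 2, 3, 4))
  f_ex <- fit_gamma_glm(d)
  expect_equal(f_ex$n_zero_excluded, 1L)
  expect_equal(f_ex$n_units, 3L)
  f_sh <- fit_gamma_glm(d, zero_policy = "half_min")
  expect_equal(f_sh$n_units, 4L)
  expect_equal(f_sh$n_zero_excluded, 0L)
  # shifted value is half the smallest positive riSD
  expect_equal(min(f_sh$data$risd), 0.2)
  expect_error(fit_gamma_glm(data.frame(risd = c(0, 0), weight = c(2, 2))),
               "no units")
})

test_that("single-unit levels trigger the unstable-SE warning", {
  d <- data.frame(risd = c(1, 1.2, 0.9, 2),
                  weight = c(2, 3, 4, 2),
                  grp = factor(c("a", "a", "a", "b")))
  expect_warning(fit_gamma_glm(d, "grp"), "single unit")
})

test_that("estimates and Wald coverage are calibrated under the model", {
  set.seed(43)
  true_mr <- 1.30
  n_units <- 2000
  reps <- 300
  est <- cover <- numeric(reps)
  for (r in seq_len(reps)) {
    w <- sample(2:10, n_units, TRUE)
    x <- rbinom(n_units, 1, 0.5)
    mu <- exp(-0.3 + log(true_mr) * x)
    kappa <- 2.5
    # precision weights: Var(y_i) = mu_i^2 / (kappa w_i)
    y <- rgamma(n_units, shape = kappa * w, rate = kappa * w / mu)
    fit <- fit_gamma_glm(data.frame(risd = y, weight = w,
                                    grp = factor(x)), "grp")
    mr <- fit$mean_ratios
    row <- mr[mr$term == "grp1", ]
    est[r] <- row$mr
    cover[r] <- row$ci_lo <= true_mr && true_mr <= row$ci_hi
  }
  expect_equal(mean(est), true_mr, tolerance = 0.05)
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.985)
})
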