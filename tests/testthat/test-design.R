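test_that("complete-case mask matches a row-wise completeness oracle", {
  cfg <- sim_config(n_participants = 250, n_waves = 8, seed = 17,
                    missing_probs = list(sex = 0, pre_health = 0,
                                         quarantine = 0,
                                         risk_perception = 0.1),
                    infection_missing_early = 0, infection_missing_late = 0)
  tab <- simulate_population(cfg)
  spec <- model_spec(fixed_terms = c("age_group", "sex", "risk_perception"),
                     spline_terms = c(day_of_year = 4L),
                     random_intercepts = "participant")
  des <- build_design(spec, tab)
  oracle <- complete.cases(tab[c("y", "age_group", "sex",
                                 "risk_perception", "day_of_year",
                                 "participant_id")])
  expect_identical(des$mask, oracle)
  expect_equal(des$n_dropped, sum(!oracle))
  expect_equal(length(des$y), sum(oracle))
})

test_that("a table without missing values keeps every row", {
  cfg <- sim_config(n_participants = 60, n_waves = 5, seed = 18,
                    missing_probs = list(sex = 0, pre_health = 0,
                                         quarantine = 0,
                                         risk_perception = 0),
                    infection_missing_early = 0, infection_missing_late = 0)
  tab <- simulate_population(cfg)
  des <- build_design(lean_model_spec("participant"), tab)
  expect_true(all(des$mask))
})

test_that("spline terms contribute df basis columns, equal for equal inputs", {
  cfg <- sim_config(n_participants = 100, n_waves = 8, seed = 19)
  tab <- simulate_population(cfg)
  spec <- model_spec(fixed_terms = "sex",
                     spline_terms = c(day_of_year = 5L),
                     random_intercepts = "participant")
  des <- build_design(spec, tab)
  basis_cols <- grep("^ns_day_of_year_", colnames(des$X))
  expect_length(basis_cols, 5L)
  yd <- des$table$day_of_year
  dup <- which(duplicated(yd) | duplicated(yd, fromLast = TRUE))
  i <- dup[yd[dup] == yd[dup][1]]
  expect_equal(des$X[i[1], basis_cols], des$X[i[2], basis_cols])
  expect_error(model_spec(spline_terms = c(day_of_year = 2L)), "df")
})

test_that("treatment contrasts use the schema reference levels", {
  cfg <- sim_config(n_participants = 150, n_waves = 6, seed = 20)
  tab <- simulate_population(cfg)
  des <- build_design(lean_model_spec("participant"), tab)
  cn <- colnames(des$X)
  expect_false(any(grepl("age_group18-44|sexmale|occupationemployed|weekdayMon",
                         cn)))
  expect_true(any(grepl("age_group0-17", cn)))
  expect_true(any(grepl("sexfemale", cn)))
})

test_that("degenerate factors and empty designs are rejected", {
  cfg <- sim_config(n_participants = 40, n_waves = 4, seed = 21)
  tab <- simulate_population(cfg)
  tab$sex <- factor("male", levels = levels(tab$sex))
  spec <- model_spec(fixed_terms = c("age_group", "sex"),
                     spline_terms = NULL,
                     random_intercepts = "participant")
  expect_error(build_design(spec, tab), "'sex'")
  tab2 <- simulate_population(cfg)
  tab2$y <- NA_integer_
  expect_error(build_design(spec, tab2), "complete-case")
})

test_that("report-week factor groups dates into Monday weeks", {
  cfg <- sim_config(n_participants = 50, n_waves = 4, seed = 22)
  tab <- simulate_population(cfg)
  spec <- model_spec(fixed_terms = "sex", spline_terms = NULL,
                     random_intercepts = c("participant", "report_week"))
  des <- build_design(spec, tab)
  wk <- as.Date(as.character(des$re$report_week))
  expect_true(all(format(wk, "%u") == "1"))
  expect_true(all(des$table$report_date - wk >= 0 &
                    des$table$report_date - wk <= 6))
})
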