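test_that("vaccination window labels and eligibility follow the offsets", {
  # dose on day 200; observations at days 150, 180, 210, 260
  t1 <- window_toy(rep(1L, 4), days_since_first_dose = c(-50, -20, 10, 60))
  w <- vaccination_windows(t1)
  expect_equal(as.character(w$observations$window_label),
               c("pre_vax", "pre_vax", "post_vax", "post_vax"))
  expect_equal(w$eligible, 1L)

  # offset 0 (the dose date) is pre-vaccination
  t0 <- window_toy(rep(1L, 4), days_since_first_dose = c(-10, 0, 5, 20))
  w0 <- vaccination_windows(t0)
  expect_equal(as.character(
    w0$observations$window_label[w0$observations$days_since_first_dose == 0]),
    "pre_vax")

  # only post-window observations -> ineligible
  tp <- window_toy(rep(2L, 3), days_since_first_dose = c(5, 20, 40))
  expect_length(vaccination_windows(tp)$eligible, 0L)

  # never-vaccinated participants are excluded entirely
  tn <- window_toy(rep(3L, 3))
  wn <- vaccination_windows(tn)
  expect_equal(nrow(wn$observations), 0L)
  expect_equal(wn$counts[["participants_never_vaccinated"]], 1L)
})

test_that("stringency boundary: SI at the threshold is strong", {
  tt <- window_toy(rep(1L, 4), SI = c(50, 49.99, 60, 30))
  w <- stringency_windows(tt)
  expect_equal(as.character(w$observations$window_label),
               c("strong_SI", "weak_SI", "strong_SI", "weak_SI"))
  expect_equal(w$eligible, 1L)
})

test_that("eligibility equals brute-force enumeration on a random table", {
  set.seed(31)
  n <- 400
  tab <- window_toy(sample(1:40, n, replace = TRUE),
                    SI = runif(n, 20, 70))
  for (th in c(45, 50, 55)) {
    spec <- window_spec("stringency", si_threshold = th)
    w <- stringency_windows(tab, spec)
    brute <- Filter(function(p) {
      si <- tab$SI[tab$participant_id == p]
      sum(si >= th) >= 2 && sum(si < th) >= 2
    }, unique(tab$participant_id))
    expect_setequal(w$eligible, brute)
    # per-row label re-evaluation
    expect_equal(as.character(w$observations$window_label),
                 ifelse(w$observations$SI >= th, "strong_SI", "weak_SI"))
  }
})

test_that("labels partition retained observations", {
  set.seed(32)
  n <- 300
  tab <- window_toy(sample(1:30, n, replace = TRUE),
                    days_since_first_dose =
                      ifelse(runif(n) < 0.3, NA, round(runif(n, -180, 180))))
  w <- vaccination_windows(tab)
  obs <- w$observations
  dd <- obs$days_since_first_dose
  expect_true(all((dd >= -100 & dd <= 0) != (dd >= 1 & dd <= 100)))
  expect_equal(nrow(obs) + w$counts[["obs_out_of_window"]], nrow(tab))
})

test_that("eligibility is monotone in min_obs and window width", {
  set.seed(33)
  n <- 500
  tab <- window_toy(sample(1:60, n, replace = TRUE),
                    days_since_first_dose = round(runif(n, -150, 150)))
  el <- lapply(c(2L, 3L, 4L), function(m)
    vaccination_windows(tab, window_spec("vaccination",
                                         min_obs_per_side = m))$eligible)
  expect_true(all(el[[2]] %in% el[[1]]))
  expect_true(all(el[[3]] %in% el[[2]]))
  narrow <- vaccination_windows(tab, window_spec("vaccination",
    pre_range = c(-40L, 0L), post_range = c(1L, 40L)))$eligible
  wide <- vaccination_windows(tab)$eligible
  expect_true(all(narrow %in% wide))
})

test_that("infection-status recode applies only up to the wave cut", {
  tab <- window_toy(1:4)
  tab$wave_index <- c(5L, 20L, 5L, 13L)
  tab$infection_status[3] <- "positive"
  out <- recode_infection_status(tab, wave_cut = 13)
  expect_equal(as.character(out$infection_status),
               c("not_tested", NA, "positive", "not_tested"))
})

test_that("sensitivity filters drop by interval cap and min_obs", {
  # gaps of 16 and 120 days: one gap over the cap of 100 -> excluded
  tab <- window_toy(c(1L, 1L, 1L, 2L, 2L, 2L),
                    report_day = c(0, 16, 136, 0, 30, 60))
  out <- apply_sensitivity_filters(tab, list(interval_cap = 100))
  expect_equal(unique(out$participant_id), 2L)
  expect_equal(attr(out, "exclusions")[["interval_cap"]], 1L)
  # median-gap rule keeps participant 1 (median of 16, 120 is 68)
  out2 <- apply_sensitivity_filters(tab, list(interval_cap = 100,
                                              gap_rule = "median_gap"))
  expect_setequal(unique(out2$participant_id), c(1L, 2L))

  out3 <- apply_sensitivity_filters(tab, list(min_obs = 4))
  expect_equal(nrow(out3), 0L)
  expect_error(apply_sensitivity_filters(tab, list(bogus = 1)),
               "unknown filter")
})

test_that("asymmetric -50/+30 window labels by its own bounds", {
  # dose day 200, observations at days 160 and 225 -> offsets -40, +25
  tab <- window_toy(c(1L, 1L, 1L, 1L),
                    days_since_first_dose = c(-40, 25, -60, 40))
  spec <- window_spec("vaccination", pre_range = c(-50L, 0L),
                      post_range = c(1L, 30L))
  w <- vaccination_windows(tab, spec)
  expect_equal(as.character(w$observations$window_label),
               c("pre_vax", "post_vax"))
  expect_equal(w$counts[["obs_out_of_window"]], 2L)
})

test_that("window_spec rejects inconsistent ranges", {
  expect_error(window_spec("vaccination", pre_range = c(0L, 10L),
                           post_range = c(5L, 20L)), "before")
  expect_error(window_spec("vaccination", min_obs_per_side = 1L), ">= 2")
})
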