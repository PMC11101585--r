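test_that("interruption dates split the periods exactly at the boundaries", {
  d <- as.Date(c("2009-07-31", "2009-08-01", "2014-05-13", "2014-05-14",
                 "2017-11-27", "2017-11-28", "2020-03-23", "2020-03-24"))
  expect_identical(assign_exposure_period(d),
                   c(NA, 1L, 1L, 2L, 2L, 3L, 3L, NA))
})

test_that("every date in the study range maps to exactly one period", {
  set.seed(3)
  d <- as.Date("2009-08-01") + sample.int(3888, 400) - 1L  # through 2020-03-23
  p <- assign_exposure_period(d)
  expect_false(anyNA(p))
  expect_true(all(p %in% 1:3))
  # inclusive on both sides: re-assigning each period's own endpoints
  per <- exposure_periods()
  expect_identical(assign_exposure_period(per$start_date), per$index)
  expect_identical(assign_exposure_period(per$end_date), per$index)
})

test_that("malformed dates and malformed period tables are rejected", {
  expect_error(assign_exposure_period("not-a-date"))
  expect_error(exposure_periods(starts = c("2009-08-01", "2014-05-15"),
                                ends = c("2014-05-13", "2020-03-23")),
               "no gaps")
  expect_error(exposure_periods(starts = "2010-01-01", ends = "2009-01-01"),
               "precedes")
})

test_that("time covariates use a 365.25-day year from the right origins", {
  rows <- data.frame(
    interview_date = as.Date(c("2009-08-01", "2014-05-14", "2015-05-14")),
    period = c(1L, 2L, 2L))
  out <- compute_time_covariates(rows)
  expect_equal(out$calendar_time[1], 0)
  expect_equal(out$time_since_period[2], 0)
  expect_equal(out$time_since_period[3], 1, tolerance = 1 / 365.25)
})

test_that("eligibility filters remove the right records and log every step", {
  toy <- toy_cohort()
  res <- apply_eligibility_filters(toy$persons, toy$observations)
  expect_identical(sort(unique(res$rows$person_id)), "P1")
  expect_identical(nrow(res$rows), 2L)   # both of P1's waves retained
  log <- res$log
  expect_identical(log$removed[log$step == "aged under 16 at interview"], 1L)
  expect_identical(log$removed[log$step == "incomplete GHQ-12 outcome"], 1L)
  expect_identical(log$removed[log$step == "missing sex or year of birth"], 1L)
  expect_identical(
    log$removed[log$step == "ethnicity outside the six in-scope groups"], 1L)
  # accounting: observations removed + remaining equals the input total
  expect_identical(log$observations_left[1] + log$removed[1],
                   nrow(toy$observations))
})

test_that("a person with one complete outcome wave keeps exactly that row", {
  toy <- toy_cohort()
  # P3 answers fully at wave 3 only
  extra <- toy$observations[1, ]
  extra$person_id <- "P3"; extra$wave <- 3L
  extra$interview_date <- as.Date("2012-06-01")
  toy$observations <- rbind(toy$observations, extra)
  res <- apply_eligibility_filters(toy$persons, toy$observations)
  p3 <- res$rows[res$rows$person_id == "P3", ]
  expect_identical(nrow(p3), 1L)
  expect_identical(p3$wave, 3L)
})

test_that("filters are idempotent", {
  cfg <- its_sim_config(n_persons = 300, seed = 5)
  coh <- simulate_cohort(cfg)
  once <- apply_eligibility_filters(coh$persons, coh$observations)
  twice <- apply_eligibility_filters(coh$persons,
                                     once$rows[names(coh$observations)])
  expect_equal(twice$rows$ghq_total, once$rows$ghq_total)
  expect_identical(nrow(twice$rows), nrow(once$rows))
  expect_true(all(twice$log$removed == 0L))
})

test_that("first-per-period keeps the earliest interview in each period", {
  cfg <- noiseless_config(n = 80, seed = 9)
  coh <- simulate_cohort(cfg)
  res <- apply_eligibility_filters(coh$persons, coh$observations,
                                   first_per_period = TRUE)
  expect_false(any(duplicated(res$rows[c("person_id", "period")])))
})
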