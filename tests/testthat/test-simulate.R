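test_that("a degenerate mixture yields a single ethnic group", {
  cfg <- its_sim_config(n_persons = 150,
                        ethnic_proportions = c(1, 0, 0, 0, 0, 0), seed = 2)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$persons$ethnicity == "White"))
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- its_sim_config(n_persons = 200, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth, b$truth)
})

test_that("the noiseless degenerate case produces constant scores", {
  coh <- simulate_cohort(noiseless_config(n = 120, seed = 3))
  totals <- score_ghq12(coh$observations[paste0("ghq", 1:12)])
  expect_true(all(totals == 10L))
})

test_that("emitted items decompose the bounded total greedily", {
  cfg <- its_sim_config(n_persons = 250, ghq_missing_prob = 0, seed = 13)
  coh <- simulate_cohort(cfg)
  items <- as.matrix(coh$observations[paste0("ghq", 1:12)])
  expect_true(all(items %in% 0:3))
  totals <- rowSums(items)
  expect_true(all(totals >= 0 & totals <= 36))
  # greedy fill: item scores never increase with item index
  expect_true(all(items[, -12] - items[, -1] >= 0))
})

test_that("group baseline means converge to the configured calibration", {
  cfg <- its_sim_config(n_persons = 20000, seed = 4)
  coh <- simulate_cohort(cfg)
  rows <- apply_eligibility_filters(coh$persons, coh$observations)$rows
  p1 <- rows[rows$period == 1L & rows$ethnicity == "White", ]
  # net of the realised year/area cluster draws (recorded in the truth map)
  # the observation-level MC error at this n is ~0.03 GHQ points
  years <- as.integer(format(as.Date(cfg$wave_windows$start[1]), "%Y"))
  years <- seq(years, max(as.integer(format(as.Date(cfg$wave_windows$end),
                                            "%Y"))))
  u <- coh$truth$year_effects[match(as.integer(format(as.Date(
    p1$interview_date), "%Y")), years)]
  v <- coh$truth$area_effects[p1$area]
  expect_equal(mean(p1$ghq_total - u - v), 11.1, tolerance = 0.1 / 11.1)
})

test_that("planted level effects equal the noiseless difference in differences", {
  lv <- planted("Black Caribbean", 2, 1.0)
  coh <- simulate_cohort(noiseless_config(n = 2500, level = lv, seed = 6))
  rows <- apply_eligibility_filters(coh$persons, coh$observations)$rows
  cell <- function(g, p) mean(rows$ghq_total[rows$ethnicity == g &
                                               rows$period == p])
  did <- (cell("Black Caribbean", 2) - cell("Black Caribbean", 1)) -
    (cell("White", 2) - cell("White", 1))
  expect_equal(did, 1.0, tolerance = 1e-12)
})

test_that("uk-born-specific planted effects appear only in their stratum", {
  mods <- list(uk_born = matrix(0, 6, 2),
               non_uk_born = planted("Black Caribbean", 2, 2.0))
  coh <- simulate_cohort(noiseless_config(n = 4000, seed = 8,
                                          level_effects_by_ukborn = mods))
  rows <- apply_eligibility_filters(coh$persons, coh$observations)$rows
  rows$uk_born_true <-
    coh$persons$uk_born[match(rows$person_id, coh$persons$person_id)]
  did <- function(ub) {
    r <- rows[rows$uk_born_true == ub, ]
    cell <- function(g, p) mean(r$ghq_total[r$ethnicity == g & r$period == p])
    (cell("Black Caribbean", 2) - cell("Black Caribbean", 1)) -
      (cell("White", 2) - cell("White", 1))
  }
  expect_equal(did("no"), 2.0, tolerance = 1e-12)
  expect_equal(did("yes"), 0.0, tolerance = 1e-12)
})

test_that("interview dates respect wave windows and waves are unique per person", {
  cfg <- its_sim_config(n_persons = 300, seed = 10)
  coh <- simulate_cohort(cfg)
  ww <- cfg$wave_windows
  d <- as.Date(coh$observations$interview_date)
  expect_true(all(d >= as.Date(ww$start)[coh$observations$wave] &
                    d <= as.Date(ww$end)[coh$observations$wave]))
  expect_false(any(duplicated(coh$observations[c("person_id", "wave")])))
})

test_that("masking is per-cell Bernoulli at the configured rate", {
  cfg <- its_sim_config(n_persons = 2500, seed = 21)
  coh <- simulate_cohort(cfg)
  set.seed(99)
  masked <- inject_missingness(coh$observations, 0.129)
  cells <- unlist(lapply(maskable_covariates(),
                         function(v) is.na(masked[[v]])))
  n_cells <- length(cells)
  expect_gt(n_cells, 1e5)
  se <- sqrt(0.129 * 0.871 / n_cells)
  expect_lt(abs(mean(cells) - 0.129), 3 * se)
})

test_that("masking preconditions and the zero-probability identity hold", {
  cfg <- its_sim_config(n_persons = 50, seed = 1)
  coh <- simulate_cohort(cfg)
  expect_identical(inject_missingness(coh$observations, 0),
                   coh$observations)
  expect_error(inject_missingness(coh$observations, 1), "\\[0, 1\\)")
  # GHQ items, sex and birth year are never masked
  masked <- inject_missingness(coh$observations, 0.9)
  expect_false(anyNA(masked$interview_date))
  expect_identical(masked[paste0("ghq", 1:12)],
                   coh$observations[paste0("ghq", 1:12)])
})

test_that("config invariants are enforced before any sampling", {
  expect_error(its_sim_config(ethnic_proportions = rep(0.2, 6)), "summing to 1")
  expect_error(its_sim_config(sigma_year = -1), "nonnegative")
  expect_error(its_sim_config(response_prob = matrix(0, 8, 3)), "\\(0, 1\\]")
  expect_error(its_sim_config(true_level_effects =
                                matrix(1, 6, 2,
                                       dimnames = list(ethnic_groups(), NULL))),
               "White row")
  expect_error(its_sim_config(covariate_missing_prob = 1), "\\[0, 1\\)")
})

test_that("a cohort round-trips through the CSV writer and reader", {
  cfg <- its_sim_config(n_persons = 60, seed = 14)
  coh <- simulate_cohort(cfg)
  coh$observations <- inject_missingness(coh$observations, cfg)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$observations$ghq1, coh$observations$ghq1)
  expect_identical(back$observations$income_group,
                   coh$observations$income_group)
  expect_equal(back$truth$secular_trend, coh$truth$secular_trend)
  unlink(dir, recursive = TRUE)
})
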