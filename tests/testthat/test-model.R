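# A small full-rank toy analysis table with known structure.
toy_pooled <- function(n = 200, seed = 1, beta_eth = 0, noise = 1) {
  set.seed(seed)
  # balance interviews across the three periods so every ethnicity-by-period
  # cell is populated even at toy sizes
  per <- exposure_periods()
  p <- sample.int(3, n, replace = TRUE)
  span <- as.numeric(per$end_date - per$start_date)[p]
  dates <- per$start_date[p] + floor(stats::runif(n) * (span + 1))
  rows <- data.frame(
    person_id = sprintf("P%04d", seq_len(n)),
    ethnicity = sample(ethnic_groups(), n, replace = TRUE),
    interview_date = dates,
    area = sample.int(5, n, replace = TRUE),
    sex = sample(c("Female", "Male"), n, replace = TRUE),
    age = sample(16:90, n, replace = TRUE),
    weight = 1)
  rows$period <- assign_exposure_period(rows$interview_date)
  rows <- compute_time_covariates(rows)
  mu <- 10 + beta_eth * (rows$ethnicity == "Black Caribbean" & rows$period == 2)
  rows$ghq_total <- round(mu + stats::rnorm(n, 0, noise))
  rows
}

lean_spec <- function(...) {
  its_model_spec(confounders = c("sex", "age"), random_effects = character(0),
                 prior_sd_coef = Inf, weighted = FALSE,
                 chains = 2L, iter = 300L, warmup = 100L, ...)
}

test_that("the design matrix enumerates the ITS coding scheme", {
  rows <- toy_pooled(400, seed = 2)
  d <- build_design_matrix(rows, its_model_spec(confounders = c("sex", "age")))
  cn <- colnames(d$X)
  expect_length(grep("^eth:[^:]+$", cn), 5)            # ethnicity main effects
  expect_length(grep("^period:", cn), 2)
  expect_length(grep("^eth:.*:period:", cn), 10)       # level interactions
  expect_length(grep("^tsp:", cn), 2)                  # per-period slopes
  expect_length(grep("^eth:.*:tsp:", cn), 10)          # slope interactions
  expect_true(all(c("(Intercept)", "time", "sex:Male", "age") %in% cn))
  # the single-common-slope option collapses the slope block to 1 + 5 columns
  d2 <- build_design_matrix(rows, its_model_spec(
    confounders = c("sex", "age"), slope_coding = "common"))
  cn2 <- colnames(d2$X)
  expect_length(grep("^tsp$", cn2), 1)
  expect_length(grep("^eth:.*:tsp$", cn2), 5)
})

test_that("reference cells code to zero and interactions are dummy products", {
  rows <- toy_pooled(100, seed = 3)
  rows$ethnicity[1] <- "White"; rows$period[1] <- 1L
  rows$time_since_period[1] <- 0.4
  rows$ethnicity[2] <- "Black Caribbean"; rows$period[2] <- 2L
  d <- build_design_matrix(rows, its_model_spec(confounders = c("sex", "age")))
  ref_cols <- grep("^(eth|period|tsp)", colnames(d$X))
  expect_true(all(d$X[1, ref_cols] == 0))
  expect_equal(unname(d$X[2, "eth:Black Caribbean"]), 1)
  expect_equal(unname(d$X[2, "period:2"]), 1)
  expect_equal(unname(d$X[2, "eth:Black Caribbean:period:2"]), 1)
  expect_equal(unname(d$X[2, "eth:Black Caribbean:tsp:2"]),
               unname(d$X[2, "tsp:2"]))
})

test_that("flat-prior posterior means reproduce the least-squares oracle", {
  rows <- toy_pooled(200, seed = 4, beta_eth = 1)
  spec <- lean_spec()
  d <- build_design_matrix(rows, spec)
  oracle <- solve(crossprod(d$X), crossprod(d$X, d$y))[, 1]
  fit <- suppressWarnings(fit_bayes_its(d, spec, seed = 9))
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-6)
})

test_that("globally rescaled weights leave the posterior unchanged", {
  rows <- toy_pooled(200, seed = 5)
  spec <- lean_spec()
  spec$weighted <- TRUE
  rows2 <- rows; rows2$weight <- 2
  f1 <- suppressWarnings(its_bayes(rows, spec, seed = 3))
  f2 <- suppressWarnings(its_bayes(rows2, spec, seed = 3))
  expect_identical(f1$draws, f2$draws)   # normalisation cancels the scale
})

test_that("tightening the coefficient prior shrinks estimates toward zero", {
  rows <- toy_pooled(150, seed = 6, beta_eth = 2)
  norms <- sapply(c(100, 1, 0.05), function(s) {
    spec <- its_model_spec(confounders = c("sex", "age"),
                           random_effects = character(0), prior_sd_coef = s,
                           weighted = FALSE, chains = 1L, iter = 400L,
                           warmup = 150L)
    fit <- suppressWarnings(its_bayes(rows, spec, seed = 2))
    sqrt(sum(coef(fit)^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("row order does not affect the fit", {
  rows <- toy_pooled(150, seed = 7)
  spec <- lean_spec()
  f1 <- suppressWarnings(its_bayes(rows, spec, seed = 4))
  f2 <- suppressWarnings(its_bayes(rows[sample.int(nrow(rows)), ], spec,
                                   seed = 4))
  expect_identical(f1$draws, f2$draws)
})

test_that("posterior quantiles are ordered within every parameter", {
  rows <- toy_pooled(150, seed = 8)
  fit <- suppressWarnings(its_bayes(rows, lean_spec(), seed = 5))
  s <- summary(fit)
  expect_true(all(s$q2.5 <= s$q50 & s$q50 <= s$q97.5))
})

test_that("random effects are estimated and diagnostics are reported", {
  cfg <- its_sim_config(n_persons = 600, seed = 19)
  rows <- small_analysis_rows(cfg)
  spec <- its_model_spec(chains = 2L, iter = 500L, warmup = 250L,
                         weighted = FALSE)
  fit <- suppressWarnings(its_bayes(rows, spec, seed = 6))
  expect_named(fit$re_summary, c("year", "area"))
  expect_identical(nrow(fit$re_summary$area), 30L)
  expect_true(all(c("sigma_resid", "sigma_year", "sigma_area") %in%
                    fit$summary$parameter))
  expect_true(all(is.finite(fit$diagnostics$rhat)))
  expect_length(fitted(fit), fit$n)
  expect_equal(fitted(fit) + residuals(fit), fit$design$y)
})

test_that("constant columns are dropped with a warning and named when missing", {
  rows <- toy_pooled(120, seed = 9)
  rows <- rows[rows$period != 3L, ]   # nobody in period 3
  spec <- lean_spec()
  expect_warning(d <- build_design_matrix(rows, spec), "period:3")
  fit <- suppressWarnings(fit_bayes_its(d, spec, seed = 1))
  expect_error(effect_table(fit), "eth:Black African:period:3")
})

test_that("the effect table carries point estimates, intervals and Ref rows", {
  rows <- toy_pooled(300, seed = 10, beta_eth = 1.5)
  fit <- suppressWarnings(its_bayes(rows, lean_spec(), seed = 7))
  et <- effect_table(fit)
  expect_identical(et$ethnicity[6], "White")
  expect_true(all(is.na(et[6, -(1:2)])))
  bc <- et[et$ethnicity == "Black Caribbean", ]
  expect_true(bc$md_p2_lo <= bc$md_p2 & bc$md_p2 <= bc$md_p2_hi)
  txt <- format(et)
  expect_identical(txt$md_period2[6], "Ref")
  expect_match(txt$md_period2[2], "^-?\\d+\\.\\d\\d \\(-?\\d+\\.\\d\\d to ")
  expect_equal(sum(et$n), nrow(rows))
})
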