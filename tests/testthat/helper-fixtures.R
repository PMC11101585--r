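# Small hand-built cohorts and configs used across tests.

# A five-person toy cohort exercising each eligibility filter:
#   P1 eligible (complete GHQ at waves 1 and 3)
#   P2 aged 15 at the interview
#   P3 never answers the GHQ-12
#   P4 missing sex
#   P5 out-of-scope ethnicity
toy_cohort <- function() {
  persons <- data.frame(
    person_id = paste0("P", 1:5),
    ethnicity = c("White", "White", "Black Caribbean", "Indian", "Chinese"),
    stratum = 1L, area = 1L,
    birth_year = c(1980L, 1995L, 1970L, 1960L, 1985L),
    sex = c("Female", "Male", "Female", NA, "Male"),
    uk_born = "yes", stringsAsFactors = FALSE)
  obs <- data.frame(
    person_id = c("P1", "P1", "P2", "P3", "P4", "P5"),
    wave = c(1L, 3L, 1L, 1L, 1L, 1L),
    interview_date = as.Date(c("2010-06-01", "2015-06-01", "2010-06-01",
                               "2010-06-01", "2010-06-01", "2010-06-01")),
    stringsAsFactors = FALSE)
  items <- matrix(1L, nrow(obs), 12,
                  dimnames = list(NULL, paste0("ghq", 1:12)))
  items[4, 5] <- NA_integer_   # P3: one absent item -> incomplete outcome
  cbind_obs <- cbind(obs, as.data.frame(items))
  cbind_obs$income_group <- "3"
  list(persons = persons, observations = cbind_obs)
}

# A noiseless simulation config: integer baselines, no trend, no random
# variation, complete response; planted effects passed through.
noiseless_config <- function(n = 600, level = matrix(0, 6, 2),
                             slope = matrix(0, 6, 2), seed = 1,
                             baseline = 10, ...) {
  its_sim_config(
    n_persons = n,
    baseline_ghq_mean = rep(baseline, 6), baseline_ghq_sd = rep(0, 6),
    sigma_year = 0, sigma_area = 0, sigma_resid = 0, secular_trend = 0,
    response_prob = matrix(1, 8, 3),
    ghq_missing_prob = 0, covariate_missing_prob = 0,
    true_level_effects = level, true_slope_effects = slope,
    seed = seed, ...)
}

# Planted-effect matrix helper: zero everywhere except one group x period.
planted <- function(group, period, value) {
  m <- matrix(0, 6, 2, dimnames = list(ethnic_groups(), c("p2", "p3")))
  m[group, period - 1L] <- value
  m
}

# Quick sampler settings for unit tests (the model defaults are longer runs).
quick_spec <- function(...) {
  its_model_spec(chains = 2L, iter = 500L, warmup = 200L, ...)
}

# Simulate, filter and weight a small cohort ready for fitting.
small_analysis_rows <- function(config, mode = "unweighted") {
  coh <- simulate_cohort(config)
  prep <- apply_eligibility_filters(coh$persons, coh$observations)
  if (mode == "unweighted") return(attach_weights(prep$rows, mode = "unweighted"))
  inc <- coh$persons[coh$persons$person_id %in% prep$rows$person_id, ]
  wt <- estimate_response_probabilities(inc, prep$rows)
  attach_weights(prep$rows, wt)
}
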