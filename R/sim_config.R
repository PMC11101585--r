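#' Default 24-month interview wave windows
#'
#' Eleven 24-month windows, the first opening Aug 1, 2009, each subsequent
#' window shifted by 12 months, so adjacent waves overlap by a year and a
#' single wave can span two exposure periods — the structure of a UK
#' household panel in which each participant is interviewed once per wave at
#' some point inside the window.
#'
#' @param n_waves number of waves.
#' @param first_start opening date of the first window.
#' @return data.frame with `wave`, `start`, `end` columns.
#' @export
default_wave_windows <- function(n_waves = 11L,
                                 first_start = as.Date("2009-08-01")) {
  starts <- seq(as.Date(first_start), by = "12 months", length.out = n_waves)
  ends <- seq(as.Date(first_start), by = "12 months",
              length.out = n_waves + 2L)[-(1:2)] - 1L
  data.frame(wave = seq_len(n_waves), start = starts, end = ends)
}

# Effect-matrix helper: 6 ethnicities x periods 2 and 3, reference row zero.
effect_matrix <- function(p2, p3) {
  m <- cbind(p2 = p2, p3 = p3)
  rownames(m) <- ethnic_groups()
  m
}

#' Configuration for the synthetic longitudinal cohort generator
#'
#' The defaults are the study conditions the generator emulates: the
#' published cohort's ethnic composition, UK-born fractions and
#' pre-interruption GHQ-12 means and SDs per group; eleven overlapping
#' 24-month wave windows from Aug 2009; non-response varying by sampling
#' stratum and exposure period; sparse item-level covariate masking
#' calibrated so roughly 87\% of included persons have complete covariates;
#' and group-by-period level and slope effects planted at the published
#' point estimates (zero for the White reference).
#'
#' `sigma_resid = NULL` (the default) derives a per-ethnicity residual SD
#' from `baseline_ghq_sd` (total SD) by removing the year and area
#' components; a scalar forces a common residual SD.
#'
#' @param n_persons cohort size.
#' @param ethnic_proportions probabilities over the six groups of
#'   [ethnic_groups()]; must sum to 1 within 1e-9.
#' @param baseline_ghq_mean,baseline_ghq_sd per-ethnicity marginal mean and
#'   SD (GHQ-12 points) of the outcome in exposure period 1.
#' @param uk_born_prob per-ethnicity probability of being UK-born.
#' @param n_strata,n_areas numbers of sampling strata and local authority
#'   areas.
#' @param wave_windows data.frame from [default_wave_windows()].
#' @param response_prob `n_strata` x 3 matrix of response probabilities in
#'   (0, 1\] by stratum (rows) and exposure period (columns).
#' @param covariate_missing_prob per-cell masking probability in \[0, 1) for
#'   [inject_missingness()].
#' @param ghq_missing_prob probability that an interview's GHQ-12 response is
#'   incomplete (some items absent), exercising the outcome-completeness
#'   filter.
#' @param true_level_effects 6 x 2 matrix (groups x periods 2-3) of planted
#'   level effects in GHQ points, relative to White and to period 1; the
#'   White row must be zero.
#' @param true_slope_effects 6 x 2 matrix of planted slope effects in GHQ
#'   points per year since the period start, same conventions.
#' @param level_effects_by_ukborn optional list with elements `uk_born` and
#'   `non_uk_born`, each a 6 x 2 level-effect matrix replacing
#'   `true_level_effects` within the stratum (used to plant effect
#'   modification by migrant status).
#' @param secular_trend linear calendar-time trend, GHQ points per year.
#' @param sigma_year,sigma_area SDs of the iid Gaussian year and area random
#'   effects (GHQ points).
#' @param sigma_resid residual SD; `NULL` derives per-ethnicity values from
#'   `baseline_ghq_sd`.
#' @param confounder_effects optional named list: covariate name ->
#'   named numeric of additive latent effects per category (defaults to no
#'   covariate effect on the outcome, which keeps the group means exactly at
#'   their configured baselines).
#' @param seed integer RNG seed.
#' @return object of class `its_sim_config`.
#' @export
its_sim_config <- function(
    n_persons = 2000L,
    ethnic_proportions = c(0.7890, 0.0434, 0.0378, 0.0543, 0.0482, 0.0273),
    baseline_ghq_mean = c(11.1, 10.3, 11.4, 10.9, 11.9, 11.7),
    baseline_ghq_sd   = c(5.4, 5.8, 6.0, 5.8, 6.3, 6.0),
    uk_born_prob      = c(0.788, 0.209, 0.615, 0.364, 0.441, 0.435),
    n_strata = 8L,
    n_areas = 30L,
    wave_windows = default_wave_windows(),
    response_prob = NULL,
    covariate_missing_prob = 0.003,
    ghq_missing_prob = 0.05,
    true_level_effects = effect_matrix(
      p2 = c(0, 0.53, 0.67, 0.35, 0.27, -0.43),
      p3 = c(0, 0.54, 1.28, 0.08, 0.52, -0.66)),
    true_slope_effects = effect_matrix(
      p2 = c(0, -0.32, -0.12, -0.19, -0.53, -0.20),
      p3 = c(0,  0.45, -0.07,  0.28,  0.25,  0.19)),
    level_effects_by_ukborn = NULL,
    secular_trend = 0,
    sigma_year = 0.4,
    sigma_area = 0.4,
    sigma_resid = NULL,
    confounder_effects = NULL,
    seed = 1L) {

  groups <- ethnic_groups()
  if (is.null(response_prob)) {
    base <- c(0.60, 0.50, 0.45)
    adj <- seq(-0.105, 0.105, length.out = n_strata)
    response_prob <- outer(adj, base, `+`)
  }
  response_prob <- as.matrix(response_prob)
  true_level_effects <- as.matrix(true_level_effects)
  true_slope_effects <- as.matrix(true_slope_effects)
  if (is.null(rownames(true_level_effects)))
    rownames(true_level_effects) <- groups
  if (is.null(rownames(true_slope_effects)))
    rownames(true_slope_effects) <- groups

  cfg <- list(
    n_persons = as.integer(n_persons),
    ethnic_proportions = stats::setNames(ethnic_proportions, groups),
    baseline_ghq_mean = stats::setNames(baseline_ghq_mean, groups),
    baseline_ghq_sd = stats::setNames(baseline_ghq_sd, groups),
    uk_born_prob = stats::setNames(uk_born_prob, groups),
    n_strata = as.integer(n_strata),
    n_areas = as.integer(n_areas),
    wave_windows = wave_windows,
    response_prob = response_prob,
    covariate_missing_prob = covariate_missing_prob,
    ghq_missing_prob = ghq_missing_prob,
    true_level_effects = true_level_effects,
    true_slope_effects = true_slope_effects,
    level_effects_by_ukborn = level_effects_by_ukborn,
    secular_trend = secular_trend,
    sigma_year = sigma_year,
    sigma_area = sigma_area,
    sigma_resid = sigma_resid,
    confounder_effects = confounder_effects,
    seed = as.integer(seed))
  class(cfg) <- "its_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_persons < 1L) stop("n_persons must be a positive integer")
    if (length(ethnic_proportions) != 6L ||
        abs(sum(ethnic_proportions) - 1) > 1e-9)
      stop("ethnic_proportions must be 6 probabilities summing to 1")
    if (any(ethnic_proportions < 0)) stop("negative ethnic proportion")
    if (any(baseline_ghq_sd < 0) || sigma_year < 0 || sigma_area < 0)
      stop("SDs and sigmas must be nonnegative")
    if (!is.null(sigma_resid) && any(sigma_resid < 0))
      stop("sigma_resid must be nonnegative")
    if (any(baseline_ghq_mean < 0 | baseline_ghq_mean > 36))
      stop("baseline GHQ means must lie in [0, 36]")
    if (any(uk_born_prob < 0 | uk_born_prob > 1))
      stop("uk_born_prob must be probabilities")
    if (n_strata < 1L || n_areas < 1L) stop("n_strata and n_areas >= 1")
    if (!all(dim(response_prob) == c(n_strata, 3L)))
      stop("response_prob must be an n_strata x 3 matrix")
    if (any(response_prob <= 0 | response_prob > 1))
      stop("response probabilities must lie in (0, 1]")
    if (covariate_missing_prob < 0 || covariate_missing_prob >= 1)
      stop("covariate_missing_prob must lie in [0, 1)")
    if (ghq_missing_prob < 0 || ghq_missing_prob >= 1)
      stop("ghq_missing_prob must lie in [0, 1)")
    if (!all(dim(true_level_effects) == c(6L, 2L)) ||
        !all(dim(true_slope_effects) == c(6L, 2L)))
      stop("effect matrices must be 6 x 2 (groups x periods 2-3)")
    if (any(true_level_effects["White", ] != 0) ||
        any(true_slope_effects["White", ] != 0))
      stop("effects are defined relative to White; the White row must be 0")
    if (is.unsorted(as.numeric(wave_windows$start)))
      stop("wave windows must be chronologically ordered")
    if (any(wave_windows$end < wave_windows$start))
      stop("wave window end precedes start")
    invisible(NULL)
  })
  invisible(cfg)
}

# Mean of a N(mu, sd^2) variable clamped to [lo, hi] (closed form).
clamped_normal_mean <- function(mu, sd, lo = 0, hi = 36) {
  if (sd == 0) return(pmin(hi, pmax(lo, mu)))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b)) +
    lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b))
}

# Latent baseline solving E[clamp(N(mu, sd_tot^2))] = target, so that the
# generated period-1 marginal mean matches the configured baseline despite
# the 0-36 bounds.
compensated_baseline <- function(target, sd_tot) {
  if (sd_tot == 0) return(target)
  stats::uniroot(function(m) clamped_normal_mean(m, sd_tot) - target,
                 interval = c(target - 4 * sd_tot, target + 4 * sd_tot),
                 tol = 1e-10)$root
}
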