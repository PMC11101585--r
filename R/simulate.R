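#' Maskable (and imputable) categorical covariates
#'
#' The categorical confounders that [inject_missingness()] may mask and
#' [chained_imputation()] may fill.  The outcome, sex, year of birth,
#' ethnicity, stratum, area and interview dates are never masked.
#' @return character vector of column names.
#' @export
maskable_covariates <- function() {
  c("urban", "relationship", "children", "education", "health_impairment",
    "housing", "imd_quintile", "employment", "income_group", "uk_born")
}

# Simple configured multinomials for the fixed categorical confounders,
# loosely matching the published cohort's marginal composition.  The joint
# distribution with ethnicity is not modelled (only uk_born varies by group).
confounder_marginals <- function() {
  list(
    sex = c(Female = 0.537, Male = 0.463),
    urban = c(urban = 0.825, rural = 0.175),
    relationship = c(in_relationship = 0.747, single = 0.253),
    children = c(`0` = 0.60, `1` = 0.20, `2+` = 0.20),
    education = c(degree = 0.33, school = 0.43, other = 0.11, none = 0.13),
    health_impairment = c(no = 0.685, yes = 0.315),
    housing = c(owned = 0.65, private_rented = 0.18, state_rented = 0.17),
    imd_quintile = c(`1` = 0.2, `2` = 0.2, `3` = 0.2, `4` = 0.2, `5` = 0.2),
    employment = c(employed = 0.527, unemployed = 0.097, retired = 0.198,
                   other = 0.178),
    income_group = c(`1` = 0.192, `2` = 0.312, `3` = 0.179, `4` = 0.118,
                     `5` = 0.085, `6` = 0.114))
}

sample_categorical <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE,
                          prob = probs / sum(probs))]
}

# Greedy decomposition of an integer total in [0, 36] into 12 items in
# {0,1,2,3}: fill items to 3 in index order, remainder to the next item.
ghq_items_from_total <- function(total) {
  items <- vapply(1:12, function(j) pmin(3L, pmax(0L, total - 3L * (j - 1L))),
                  integer(length(total)))
  if (length(total) == 1L) matrix(items, nrow = 1L) else items
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Simulates a UK-household-panel-like cohort: person-level attributes
#' (ethnicity, sampling stratum, local authority area, birth year, UK-born
#' and categorical confounders drawn from configured multinomials), one
#' candidate interview per person and wave at a uniform date inside the wave
#' window, kept with the configured stratum-by-period response probability,
#' and a GHQ-12 outcome generated from the linear interrupted-time-series
#' model the package fits:
#' latent mean = compensated group baseline + secular trend x calendar time
#' + planted group-by-period level effect + planted group-by-period slope
#' effect x time since period start + year random effect + area random
#' effect (+ any configured covariate effects); the observed total is the
#' latent mean plus Gaussian noise, rounded and clamped to \[0, 36\], and
#' decomposed into 12 item scores that sum to it exactly.
#'
#' The baseline intercept per group is solved so that the post-clamping
#' period-1 marginal mean equals the configured baseline (see
#' `clamped_normal_mean`); clamping counts are recorded in the truth map.
#' Identical config and seed give identical output.
#'
#' @param config an [its_sim_config()] object.
#' @return list with `persons` (one row per person), `observations` (one row
#'   per realised interview, covariates copied onto rows so that masking can
#'   act per cell) and `truth` (flat named list of every planted parameter,
#'   the realised year/area effects and clamping counts).
#' @export
simulate_cohort <- function(config = its_sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  groups <- ethnic_groups()
  n <- config$n_persons
  ww <- config$wave_windows
  origin <- as.Date(ww$start[1L])
  start_year <- as.integer(format(origin, "%Y"))
  end_year <- as.integer(format(max(as.Date(ww$end)), "%Y"))
  years <- start_year:end_year

  marg <- confounder_marginals()
  persons <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    ethnicity = sample(groups, n, replace = TRUE,
                       prob = config$ethnic_proportions),
    stratum = sample.int(config$n_strata, n, replace = TRUE),
    area = sample.int(config$n_areas, n, replace = TRUE),
    sex = sample_categorical(n, marg$sex),
    stringsAsFactors = FALSE)
  # ages 15-89 at study start: a small under-16 fringe exercises the filters
  persons$birth_year <- start_year - sample(15:89, n, replace = TRUE)
  persons$uk_born <- ifelse(
    stats::rbinom(n, 1L, config$uk_born_prob[persons$ethnicity]) == 1L,
    "yes", "no")
  for (v in setdiff(maskable_covariates(), "uk_born"))
    persons[[v]] <- sample_categorical(n, marg[[v]])

  gi <- match(persons$ethnicity, groups)
  sd_resid <- if (is.null(config$sigma_resid)) {
    v <- config$baseline_ghq_sd^2 - config$sigma_year^2 - config$sigma_area^2
    if (any(v < 0))
      stop("baseline_ghq_sd smaller than the year/area components")
    sqrt(v)
  } else rep(config$sigma_resid, 6L)[1:6]
  names(sd_resid) <- groups
  sd_tot <- sqrt(sd_resid^2 + config$sigma_year^2 + config$sigma_area^2)
  base_adj <- vapply(seq_along(groups), function(g)
    compensated_baseline(config$baseline_ghq_mean[g], sd_tot[g]), 0)
  names(base_adj) <- groups

  u_year <- stats::rnorm(length(years), 0, config$sigma_year)
  names(u_year) <- years
  v_area <- stats::rnorm(config$n_areas, 0, config$sigma_area)

  periods <- exposure_periods()
  n_wave <- nrow(ww)
  pidx <- rep(seq_len(n), times = n_wave)
  widx <- rep(seq_len(n_wave), each = n)
  span <- as.numeric(as.Date(ww$end) - as.Date(ww$start))[widx]
  date <- as.Date(ww$start)[widx] + floor(stats::runif(length(widx)) * (span + 1))

  per <- assign_exposure_period(date, periods)
  per_eff <- ifelse(is.na(per), 3L, per)  # post-study dates: last period's rate
  respond <- stats::runif(length(pidx)) <
    config$response_prob[cbind(persons$stratum[pidx], per_eff)]

  pidx <- pidx[respond]; widx <- widx[respond]
  date <- date[respond]; per <- per[respond]; per_eff <- per_eff[respond]

  t_cal <- as.numeric(date - origin) / 365.25
  tsp <- as.numeric(date - periods$start_date[per_eff]) / 365.25
  eth_i <- gi[pidx]

  lev <- config$true_level_effects
  if (!is.null(config$level_effects_by_ukborn)) {
    ub <- persons$uk_born[pidx] == "yes"
    lev_uk <- config$level_effects_by_ukborn$uk_born
    lev_non <- config$level_effects_by_ukborn$non_uk_born
    level_eff <- ifelse(per_eff >= 2L,
                        ifelse(ub, lev_uk[cbind(eth_i, pmax(per_eff - 1L, 1L))],
                               lev_non[cbind(eth_i, pmax(per_eff - 1L, 1L))]),
                        0)
  } else {
    level_eff <- ifelse(per_eff >= 2L,
                        lev[cbind(eth_i, pmax(per_eff - 1L, 1L))], 0)
  }
  slope_eff <- ifelse(per_eff >= 2L,
                      config$true_slope_effects[cbind(eth_i,
                                                      pmax(per_eff - 1L, 1L))],
                      0)

  mu <- base_adj[eth_i] + config$secular_trend * t_cal + level_eff +
    slope_eff * tsp +
    u_year[as.character(as.integer(format(date, "%Y")))] +
    v_area[persons$area[pidx]]

  if (!is.null(config$confounder_effects)) {
    for (v in names(config$confounder_effects)) {
      eff <- config$confounder_effects[[v]]
      val <- persons[[v]][pidx]
      mu <- mu + ifelse(val %in% names(eff), eff[val], 0)
    }
  }

  latent <- mu + stats::rnorm(length(mu), 0, sd_resid[eth_i])
  rounded <- round(latent)
  total <- pmin(36L, pmax(0L, as.integer(rounded)))
  n_clamp_low <- sum(rounded < 0)
  n_clamp_high <- sum(rounded > 36)

  items <- ghq_items_from_total(total)
  colnames(items) <- paste0("ghq", 1:12)

  # some interviews omit part of the GHQ-12 questionnaire
  if (config$ghq_missing_prob > 0 && length(total)) {
    inc <- stats::runif(length(total)) < config$ghq_missing_prob
    if (any(inc)) {
      sub <- which(inc)
      mask <- matrix(stats::runif(length(sub) * 12L) < 0.5, length(sub), 12L)
      none <- rowSums(mask) == 0L
      mask[none, 1L] <- TRUE
      im <- items[sub, , drop = FALSE]
      im[mask] <- NA_integer_
      items[sub, ] <- im
    }
  }

  observations <- data.frame(
    person_id = persons$person_id[pidx],
    wave = ww$wave[widx],
    interview_date = date,
    stringsAsFactors = FALSE)
  observations <- cbind(observations, as.data.frame(items))
  for (v in maskable_covariates())
    observations[[v]] <- persons[[v]][pidx]
  o <- order(observations$person_id, observations$interview_date)
  observations <- observations[o, , drop = FALSE]
  rownames(observations) <- NULL

  truth <- c(
    as.list(stats::setNames(config$baseline_ghq_mean,
                            paste0("baseline_mean_", make.names(groups)))),
    as.list(stats::setNames(base_adj,
                            paste0("latent_baseline_", make.names(groups)))),
    as.list(stats::setNames(as.vector(config$true_level_effects),
                            paste0("level_", rep(make.names(groups), 2),
                                   "_p", rep(2:3, each = 6)))),
    as.list(stats::setNames(as.vector(config$true_slope_effects),
                            paste0("slope_", rep(make.names(groups), 2),
                                   "_p", rep(2:3, each = 6)))),
    list(secular_trend = config$secular_trend,
         sigma_year = config$sigma_year,
         sigma_area = config$sigma_area,
         sigma_resid = unname(sd_resid),
         year_effects = unname(u_year),
         area_effects = unname(v_area),
         n_clamped_low = n_clamp_low,
         n_clamped_high = n_clamp_high,
         seed = config$seed))

  list(persons = persons, observations = observations, truth = truth)
}

#' Mask covariate cells completely at random
#'
#' Each maskable covariate cell of the observation table is independently set
#' to `NA` with probability `config$covariate_missing_prob`.  GHQ items, sex,
#' birth year, ethnicity and design identifiers are never masked by this
#' operation.
#'
#' @param observations observation table from [simulate_cohort()].
#' @param config an [its_sim_config()] (only `covariate_missing_prob` is
#'   used), or a bare probability in \[0, 1).
#' @return `observations` with masked cells.
#' @export
inject_missingness <- function(observations, config) {
  p <- if (inherits(config, "its_sim_config")) config$covariate_missing_prob
       else config
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 1)
    stop("covariate_missing_prob must lie in [0, 1)")
  if (p == 0) return(observations)
  for (v in intersect(maskable_covariates(), names(observations))) {
    hit <- stats::runif(nrow(observations)) < p
    observations[[v]][hit] <- NA
  }
  observations
}
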