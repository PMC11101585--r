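run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the main interrupted-time-series analysis end to end
#'
#' Executes score -> eligibility filters -> inverse-probability weights ->
#' chained imputation with mode pooling -> Bayesian ITS fit -> effect table.
#' Deterministic under a fixed seed.  Any stage failure aborts with the
#' stage name.
#'
#' @param cohort list with `persons` and `observations` (e.g. from
#'   [simulate_cohort()], with missingness from [inject_missingness()]).
#' @param model_spec an [its_model_spec()].
#' @param imp_config an [impute_config()]; its seed is derived from `seed`.
#' @param periods period table from [exposure_periods()].
#' @param seed integer seed governing imputation and the sampler.
#' @param impute run the imputation stage (complete-case callers disable it).
#' @return object of class `its_analysis`: list with `fit`, `effects`,
#'   `pooled`, `weights`, `exclusions` and `n_persons`.
#' @export
run_main <- function(cohort, model_spec = its_model_spec(),
                     imp_config = impute_config(),
                     periods = exposure_periods(), seed = 1L,
                     impute = TRUE) {
  prep <- run_stage("eligibility filters",
                    apply_eligibility_filters(cohort$persons,
                                              cohort$observations, periods))
  if (!nrow(prep$rows)) stop("pipeline stage 'eligibility filters': ",
                             "no rows survive the filters")
  inc <- cohort$persons[cohort$persons$person_id %in% prep$rows$person_id, ]
  wt <- run_stage("response weights",
                  estimate_response_probabilities(inc, prep$rows,
                                                  periods$index))
  rows <- run_stage("attach weights",
                    attach_weights(prep$rows, wt,
                                   mode = if (model_spec$weighted) "weighted"
                                          else "unweighted"))
  if (impute) {
    imp_config$seed <- as.integer(seed)
    imp <- run_stage("chained imputation", chained_imputation(rows, imp_config))
    pooled <- run_stage("mode pooling", pool_by_mode(imp))
  } else {
    pooled <- rows
  }
  fit <- run_stage("Bayesian ITS fit", its_bayes(pooled, model_spec, seed))
  structure(list(fit = fit, effects = effect_table(fit), pooled = pooled,
                 weights = wt, exclusions = prep$log,
                 n_persons = length(unique(pooled$person_id))),
            class = "its_analysis")
}

#' @export
print.its_analysis <- function(x, ...) {
  cat(sprintf("ITS analysis: %d persons, %d person-interviews\n\n",
              x$n_persons, nrow(x$pooled)))
  print(x$effects, ...)
  invisible(x)
}

#' Stratified re-analysis by migrant status or household income
#'
#' Refits the main model independently on each stratum of the pooled,
#' weighted dataset (the model specification and the weights are those of
#' the main run; only the row subset changes).  Within each stratum the
#' reference group is the stratum's own White participants.  The income
#' split dichotomises the ordinal net-household-income code at its median
#' over the analysis cohort; rows at the exact median fall in the lower
#' stratum.
#'
#' @param main an `its_analysis` from [run_main()].
#' @param stratifier `"uk_born"` or `"income"`.
#' @param seed integer seed.
#' @return named list of two `its_analysis`-like lists (`fit`, `effects`,
#'   `n_persons`), one per stratum; an empty stratum is an error.
#' @export
run_stratified <- function(main, stratifier = c("uk_born", "income"),
                           seed = 1L) {
  stratifier <- match.arg(stratifier)
  pooled <- main$pooled
  if (stratifier == "uk_born") {
    if (anyNA(pooled$uk_born))
      stop("uk_born must be complete (imputed) before stratification")
    split_by <- ifelse(pooled$uk_born == "yes", "uk_born", "non_uk_born")
  } else {
    code <- as.integer(pooled$income_group)
    med <- stats::median(code)
    split_by <- ifelse(code <= med, "low_income", "high_income")
  }
  lv <- if (stratifier == "uk_born") c("uk_born", "non_uk_born")
        else c("low_income", "high_income")
  out <- lapply(lv, function(s) {
    sub <- pooled[split_by == s, , drop = FALSE]
    if (!nrow(sub)) stop("empty stratum: ", s)
    fit <- its_bayes(sub, main$fit$spec, seed)
    list(fit = fit, effects = effect_table(fit),
         n_persons = length(unique(sub$person_id)))
  })
  stats::setNames(out, lv)
}

#' Sensitivity analyses
#'
#' Repeats the main analysis (i) without weights, (ii) on complete cases
#' (persons with no missing covariate cell anywhere, imputation skipped), or
#' (iii) restricted to persons who responded at least once in every exposure
#' period.
#'
#' @param cohort as in [run_main()].
#' @param which `"unweighted"`, `"complete_case"` or `"all_periods"`.
#' @param model_spec,imp_config,periods,seed as in [run_main()].
#' @return an `its_analysis`.
#' @export
run_sensitivity <- function(cohort,
                            which = c("unweighted", "complete_case",
                                      "all_periods"),
                            model_spec = its_model_spec(),
                            imp_config = impute_config(),
                            periods = exposure_periods(), seed = 1L) {
  which <- match.arg(which)
  if (which == "unweighted") {
    model_spec$weighted <- FALSE
    return(run_main(cohort, model_spec, imp_config, periods, seed))
  }
  if (which == "complete_case") {
    obs <- cohort$observations
    vars <- intersect(maskable_covariates(), names(obs))
    has_miss <- rowSums(is.na(obs[vars])) > 0L
    drop_ids <- unique(obs$person_id[has_miss])
    cohort$observations <- obs[!(obs$person_id %in% drop_ids), , drop = FALSE]
    return(run_main(cohort, model_spec, imp_config, periods, seed,
                    impute = FALSE))
  }
  # all_periods: persons with at least one eligible response in each period
  prep <- apply_eligibility_filters(cohort$persons, cohort$observations,
                                    periods)
  tab <- table(prep$rows$person_id,
               factor(prep$rows$period, levels = periods$index))
  keep_ids <- rownames(tab)[apply(tab > 0L, 1L, all)]
  cohort$observations <-
    cohort$observations[cohort$observations$person_id %in% keep_ids, ,
                        drop = FALSE]
  cohort$persons <- cohort$persons[cohort$persons$person_id %in% keep_ids, ,
                                   drop = FALSE]
  run_main(cohort, model_spec, imp_config, periods, seed)
}

#' Descriptive cohort table by ethnic group
#'
#' Counts and percentages per ethnic group for each categorical
#' characteristic (with missing counted as its own level and percentages
#' reported against both the column total and the non-missing denominator),
#' median (IQR) for age and the per-person number of responses, the share of
#' persons present in every exposure period, the share with complete
#' covariate data, and the exposure-period-1 GHQ-12 mean (SD).
#' Chi-squared / Kruskal-Wallis / t tests comparing each minoritised group
#' with the reference are attached as descriptive annotations only.
#'
#' Each person's categorical values are taken from their earliest analysis
#' row.
#'
#' @param rows analysis table from [apply_eligibility_filters()].
#' @param reference reference ethnicity for the test annotations.
#' @return list of class `its_descriptive` with elements `totals`,
#'   `characteristics`, `continuous`, `ghq_baseline`, `shares`, `tests`.
#' @export
make_descriptive_table <- function(rows, reference = "White") {
  o <- order(rows$person_id, as.Date(rows$interview_date))
  first <- rows[o, ][!duplicated(rows$person_id[o]), ]
  groups <- intersect(ethnic_groups(), unique(first$ethnicity))
  eth <- factor(first$ethnicity, levels = groups)
  n_tot <- as.vector(table(eth))

  totals <- data.frame(ethnicity = groups, n = n_tot,
                       pct = 100 * n_tot / sum(n_tot))

  vars <- intersect(c("sex", maskable_covariates()), names(first))
  chr <- list(); tests <- list()
  for (v in vars) {
    x <- as.character(first[[v]])
    lev <- c(sort(unique(x[!is.na(x)])), "missing")
    x[is.na(x)] <- "missing"
    tab <- table(factor(x, levels = lev), eth)
    nonmiss <- colSums(tab[lev != "missing", , drop = FALSE])
    for (l in lev) {
      cnt <- as.vector(tab[l, ])
      chr[[length(chr) + 1L]] <- data.frame(
        characteristic = v, level = l, ethnicity = groups, n = cnt,
        pct_total = 100 * cnt / n_tot,
        pct_nonmissing = if (l == "missing") NA_real_
                         else 100 * cnt / pmax(nonmiss, 1L))
    }
    for (g in setdiff(groups, reference)) {
      sub <- x[eth %in% c(reference, g)] != "missing"
      t2 <- table(x[eth %in% c(reference, g)][sub],
                  droplevels(eth[eth %in% c(reference, g)][sub]))
      p <- tryCatch(suppressWarnings(stats::chisq.test(t2)$p.value),
                    error = function(e) NA_real_)
      tests[[length(tests) + 1L]] <- data.frame(
        characteristic = v, ethnicity = g, test = "chi-squared", p_value = p)
    }
  }

  age0 <- first$age
  resp_per_person <- tapply(rows$person_id, rows$person_id, length)
  resp_eth <- first$ethnicity[match(names(resp_per_person), first$person_id)]
  cont <- rbind(
    do.call(rbind, lapply(groups, function(g) {
      q <- stats::quantile(age0[eth == g], c(0.25, 0.5, 0.75), na.rm = TRUE)
      data.frame(characteristic = "age", ethnicity = g,
                 median = q[2L], q1 = q[1L], q3 = q[3L])
    })),
    do.call(rbind, lapply(groups, function(g) {
      q <- stats::quantile(resp_per_person[resp_eth == g],
                           c(0.25, 0.5, 0.75), na.rm = TRUE)
      data.frame(characteristic = "responses", ethnicity = g,
                 median = q[2L], q1 = q[1L], q3 = q[3L])
    })))
  rownames(cont) <- NULL
  for (g in setdiff(groups, reference)) {
    kw <- tryCatch(stats::kruskal.test(
      list(age0[eth == reference], age0[eth == g]))$p.value,
      error = function(e) NA_real_)
    tests[[length(tests) + 1L]] <- data.frame(
      characteristic = "age", ethnicity = g, test = "kruskal-wallis",
      p_value = kw)
  }

  p1 <- rows[rows$period == 1L, ]
  ghq <- do.call(rbind, lapply(groups, function(g) {
    y <- p1$ghq_total[p1$ethnicity == g]
    data.frame(ethnicity = g, n_obs = length(y),
               mean = if (length(y)) mean(y) else NA_real_,
               sd = if (length(y) > 1L) stats::sd(y) else NA_real_)
  }))
  for (g in setdiff(groups, reference)) {
    tt <- tryCatch(stats::t.test(p1$ghq_total[p1$ethnicity == reference],
                                 p1$ghq_total[p1$ethnicity == g])$p.value,
                   error = function(e) NA_real_)
    tests[[length(tests) + 1L]] <- data.frame(
      characteristic = "ghq_baseline", ethnicity = g, test = "t",
      p_value = tt)
  }

  per_tab <- table(rows$person_id, rows$period)
  all_period_ids <- rownames(per_tab)[rowSums(per_tab > 0L) == 3L]
  vars_mask <- intersect(maskable_covariates(), names(rows))
  cc_by_person <- tapply(rowSums(is.na(rows[vars_mask])) == 0L,
                         rows$person_id, all)
  shares <- do.call(rbind, lapply(groups, function(g) {
    ids <- first$person_id[eth == g]
    data.frame(ethnicity = g,
               present_all_periods = 100 * mean(ids %in% all_period_ids),
               complete_covariates = 100 * mean(cc_by_person[ids]))
  }))

  structure(list(totals = totals,
                 characteristics = do.call(rbind, chr),
                 continuous = cont, ghq_baseline = ghq, shares = shares,
                 tests = do.call(rbind, tests)),
            class = "its_descriptive")
}

#' @export
print.its_descriptive <- function(x, ...) {
  cat("Cohort composition:\n")
  print(transform(x$totals, pct = sprintf("%.1f%%", pct)),
        row.names = FALSE)
  cat("\nExposure-period-1 GHQ-12 mean (SD):\n")
  print(transform(x$ghq_baseline, mean = round(mean, 1), sd = round(sd, 1)),
        row.names = FALSE)
  cat("\n(characteristics, continuous, shares and tests in the object)\n")
  invisible(x)
}
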