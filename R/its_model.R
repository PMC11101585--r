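#' Specification of the Bayesian interrupted-time-series model
#'
#' Defines the coefficient layout, priors, random effects, weighting and
#' sampler settings of the ITS linear model: main effects for ethnicity,
#' exposure period and all confounders, a linear calendar-time trend,
#' per-period time-since-interruption slopes, ethnicity-by-period and
#' ethnicity-by-slope interactions, and iid Gaussian random effects for
#' calendar year and local authority area.
#'
#' @param reference_ethnicity the comparison group (default `"White"`).
#' @param period_coding `"vs-baseline"` (periods 2 and 3 each contrasted
#'   against period 1, so the period-3 contrast is cumulative since the
#'   pre-interruption era — the default, matching how the published period-3
#'   effects exceed the period-2 ones) or `"sequential"` (the period-3
#'   indicator switches on from period 3 only, so its coefficient is the
#'   increment over period 2).
#' @param slope_coding `"per-period"` (default: separate time-since-start
#'   slopes for periods 2 and 3, each interacted with ethnicity, matching the
#'   reported per-period slope columns) or `"common"` (a single
#'   time-since-interruption slope shared by periods 2 and 3, five
#'   ethnicity-interaction slope columns in total).
#' @param confounders column names entered as fixed-effect adjustments;
#'   categorical columns are dummy-coded against their first sorted level,
#'   numeric columns enter linearly.
#' @param random_effects subset of `c("year", "area")`; iid Gaussian blocks.
#'   Year levels are the interview calendar years; unobserved levels within
#'   the span keep their prior.
#' @param person_intercept add an iid Gaussian person-level intercept
#'   (defaults off: the emulated analysis models residual temporal and
#'   spatial confounding only).
#' @param prior_sd_coef weakly informative Normal(0, sd^2) prior scale for
#'   all fixed-effect coefficients, in GHQ points (`Inf` for a flat prior).
#' @param prior_sd_sd half-Normal scale for the residual and random-effect
#'   SDs, in GHQ points.
#' @param weighted use the per-row inverse-probability weights as
#'   log-likelihood multipliers (they are normalised to mean 1 internally, so
#'   a global rescaling of the weights cancels exactly).
#' @param chains,iter,warmup Gibbs sampler settings: number of chains, total
#'   iterations per chain, and warmup iterations discarded per chain.
#' @return object of class `its_model_spec`.
#' @export
its_model_spec <- function(reference_ethnicity = "White",
                           period_coding = c("vs-baseline", "sequential"),
                           slope_coding = c("per-period", "common"),
                           confounders = c("sex", "age",
                                           maskable_covariates()),
                           random_effects = c("year", "area"),
                           person_intercept = FALSE,
                           prior_sd_coef = 10,
                           prior_sd_sd = 5,
                           weighted = TRUE,
                           chains = 4L, iter = 2000L, warmup = 1000L) {
  if (prior_sd_coef <= 0 || prior_sd_sd <= 0) stop("prior scales must be > 0")
  if (warmup >= iter) stop("warmup must be smaller than iter")
  structure(list(reference_ethnicity = reference_ethnicity,
                 period_coding = match.arg(period_coding),
                 slope_coding = match.arg(slope_coding),
                 confounders = confounders,
                 random_effects = intersect(random_effects, c("year", "area")),
                 person_intercept = isTRUE(person_intercept),
                 prior_sd_coef = prior_sd_coef, prior_sd_sd = prior_sd_sd,
                 weighted = isTRUE(weighted),
                 chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup)),
            class = "its_model_spec")
}

#' Build the ITS design matrix
#'
#' Dummy-codes the pooled analysis table into the fixed-effect matrix with
#' deterministic column names, plus the outcome, weight and random-effect
#' index vectors.  Constant columns after coding are dropped with a warning;
#' remaining rank deficiency is an error.
#'
#' @param pooled analysis table with no missing cells in the used columns
#'   (`ghq_total`, `ethnicity`, `period`, `calendar_time`,
#'   `time_since_period`, confounders, `weight` if weighted, and
#'   `interview_date`/`area`/`person_id` for the random effects).
#' @param spec an [its_model_spec()].
#' @return list with `y`, `w`, `X`, `re_index` (named list of 1-based index
#'   vectors), `re_levels` (their level labels) and `dropped` (names of
#'   constant columns removed).
#' @export
build_design_matrix <- function(pooled, spec = its_model_spec()) {
  used <- c("ghq_total", "ethnicity", "period", "calendar_time",
            "time_since_period", intersect(spec$confounders, names(pooled)))
  miss <- used[vapply(used, function(v) anyNA(pooled[[v]]), TRUE)]
  if (length(miss))
    stop("pooled data has missing cells in: ", paste(miss, collapse = ", "))

  eth_levels <- c(spec$reference_ethnicity,
                  setdiff(ethnic_groups(), spec$reference_ethnicity))
  eth <- factor(pooled$ethnicity, levels = eth_levels)
  if (anyNA(eth)) stop("ethnicity outside the in-scope groups")
  per <- as.integer(pooled$period)
  tsp <- pooled$time_since_period

  p2 <- if (spec$period_coding == "vs-baseline") as.numeric(per == 2L)
        else as.numeric(per >= 2L)
  p3 <- as.numeric(per == 3L)
  if (spec$period_coding == "sequential") p3 <- as.numeric(per >= 3L)

  cols <- list(`(Intercept)` = rep(1, nrow(pooled)),
               time = pooled$calendar_time,
               `period:2` = p2, `period:3` = p3)
  if (spec$slope_coding == "per-period") {
    cols[["tsp:2"]] <- tsp * (per == 2L)
    cols[["tsp:3"]] <- tsp * (per == 3L)
  } else {
    cols[["tsp"]] <- tsp * (per >= 2L)
  }
  for (g in eth_levels[-1L]) {
    eg <- as.numeric(eth == g)
    cols[[paste0("eth:", g)]] <- eg
    cols[[paste0("eth:", g, ":period:2")]] <- eg * p2
    cols[[paste0("eth:", g, ":period:3")]] <- eg * p3
    if (spec$slope_coding == "per-period") {
      cols[[paste0("eth:", g, ":tsp:2")]] <- eg * cols[["tsp:2"]]
      cols[[paste0("eth:", g, ":tsp:3")]] <- eg * cols[["tsp:3"]]
    } else {
      cols[[paste0("eth:", g, ":tsp")]] <- eg * cols[["tsp"]]
    }
  }
  for (v in intersect(spec$confounders, names(pooled))) {
    x <- pooled[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- x
    } else {
      lev <- sort(unique(as.character(x)))
      for (l in lev[-1L])
        cols[[paste0(v, ":", l)]] <- as.numeric(x == l)
    }
  }

  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- apply(X, 2L, function(c) length(unique(c)) == 1L)
  const["(Intercept)"] <- FALSE
  dropped <- colnames(X)[const]
  if (length(dropped)) {
    warning("dropping constant design columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("design matrix is rank deficient (rank ", qrx$rank, " of ",
         ncol(X), ")")

  re_index <- list(); re_levels <- list()
  if ("year" %in% spec$random_effects) {
    yr <- as.integer(format(as.Date(pooled$interview_date), "%Y"))
    lev <- seq(min(yr), max(yr))
    re_index$year <- match(yr, lev)
    re_levels$year <- as.character(lev)
  }
  if ("area" %in% spec$random_effects) {
    lev <- sort(unique(pooled$area))
    re_index$area <- match(pooled$area, lev)
    re_levels$area <- as.character(lev)
  }
  if (spec$person_intercept) {
    lev <- sort(unique(pooled$person_id))
    re_index$person <- match(pooled$person_id, lev)
    re_levels$person <- as.character(lev)
  }

  if (spec$weighted && !("weight" %in% names(pooled)))
    stop("spec requests a weighted fit but the data carry no weight column; ",
         "attach weights first or set weighted = FALSE")
  w <- if (spec$weighted) pooled$weight else rep(1, nrow(pooled))
  if (anyNA(w) || any(w <= 0)) stop("weights must be positive")

  list(y = as.numeric(pooled$ghq_total), w = as.numeric(w), X = X,
       re_index = re_index, re_levels = re_levels, dropped = dropped)
}

# Split-chain potential-scale-reduction statistic (split R-hat).
split_rhat <- function(draws_by_chain) {
  halves <- unlist(lapply(draws_by_chain, function(x) {
    h <- length(x) %/% 2L
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars); B <- n * stats::var(means)
  if (W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via the initial positive autocorrelation sequence.
ess_basic <- function(draws_by_chain) {
  n <- length(draws_by_chain[[1L]]); m <- length(draws_by_chain)
  if (stats::var(unlist(draws_by_chain)) < 1e-12) return(n * m)
  rho <- rep(0, n - 1L)
  acfs <- lapply(draws_by_chain, function(x)
    stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L])
  k <- length(acfs[[1L]])
  rho[seq_len(k)] <- Reduce(`+`, acfs) / m
  s <- 0
  for (t in seq(1L, k - 1L, by = 2L)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    s <- s + pair
  }
  n * m / (1 + 2 * s)
}

#' Fit the Bayesian ITS model on prepared design outputs
#'
#' Runs the in-package Gaussian-conjugate Gibbs sampler (see the package
#' vignette) on the outputs of [build_design_matrix()]: weighted Gaussian
#' likelihood, Normal(0, `prior_sd_coef`^2) coefficient priors, half-Normal
#' SD priors, and conjugate updates for the coefficient and random-effect
#' blocks with slice-sampled standard deviations.  Weights are normalised to
#' mean 1.  Posterior means of the coefficients are Rao-Blackwellised
#' (averages of the exact conditional means), so with a flat prior, unit
#' weights and no random effects they reproduce the weighted-least-squares
#' solution to numerical precision.  Split R-hat and effective sample sizes
#' are computed per parameter; a run with max R-hat above 1.05 is flagged
#' (`converged = FALSE`) with a warning, never returned silently.
#'
#' @param design output of [build_design_matrix()].
#' @param spec an [its_model_spec()].
#' @param seed integer seed.
#' @return object of class `its_bayes` (see [its_bayes()]).
#' @export
fit_bayes_its <- function(design, spec = its_model_spec(), seed = 1L) {
  w <- design$w * length(design$w) / sum(design$w)
  set.seed(seed)
  chains <- lapply(seq_len(spec$chains), function(ch)
    gibbs_lmm_cpp(design$y, design$X, w, unname(design$re_index),
                  vapply(design$re_levels, length, 0L),
                  spec$iter, spec$warmup, spec$prior_sd_coef,
                  spec$prior_sd_sd, spec$prior_sd_sd))

  pnames <- colnames(design$X)
  re_names <- names(design$re_index)
  sd_names <- c("sigma_resid", if (length(re_names))
    paste0("sigma_", re_names))
  beta <- do.call(rbind, lapply(chains, `[[`, "beta"))
  colnames(beta) <- pnames
  cmean <- do.call(rbind, lapply(chains, `[[`, "beta_condmean"))
  sds <- do.call(rbind, lapply(chains, function(c)
    cbind(c$sigma, if (length(re_names)) c$tau)))
  colnames(sds) <- sd_names

  draws <- cbind(beta, sds)
  by_chain <- function(j, mat_name) lapply(chains, function(c) {
    m <- if (mat_name == "beta") c$beta
         else cbind(c$sigma, if (length(re_names)) c$tau)
    m[, j]
  })
  diag_df <- data.frame(
    parameter = colnames(draws),
    rhat = c(vapply(seq_along(pnames), function(j)
               split_rhat(by_chain(j, "beta")), 0),
             vapply(seq_along(sd_names), function(j)
               split_rhat(by_chain(j, "sd")), 0)),
    ess = c(vapply(seq_along(pnames), function(j)
              ess_basic(by_chain(j, "beta")), 0),
            vapply(seq_along(sd_names), function(j)
              ess_basic(by_chain(j, "sd")), 0)))

  q <- t(apply(draws, 2L, stats::quantile, c(0.025, 0.5, 0.975)))
  summ <- data.frame(
    parameter = colnames(draws),
    mean = c(colMeans(cmean), colMeans(sds)),
    sd = apply(draws, 2L, stats::sd),
    q2.5 = q[, 1L], q50 = q[, 2L], q97.5 = q[, 3L],
    rhat = diag_df$rhat, ess = diag_df$ess, row.names = NULL)

  re_summary <- lapply(seq_along(re_names), function(r) {
    u <- do.call(rbind, lapply(chains, function(c) c$u[[r]]))
    data.frame(level = design$re_levels[[r]], mean = colMeans(u),
               sd = apply(u, 2L, stats::sd))
  })
  names(re_summary) <- re_names

  converged <- all(is.finite(diag_df$rhat)) && max(diag_df$rhat) < 1.05
  if (!converged)
    warning("sampler did not pass convergence checks (max split R-hat = ",
            round(max(diag_df$rhat), 3), "); inspect the draws")

  structure(list(summary = summ, draws = draws, coef_names = pnames,
                 re_summary = re_summary, diagnostics = diag_df,
                 converged = converged, spec = spec, design = design,
                 seed = seed, n = length(design$y)),
            class = "its_bayes")
}

#' Fit the Bayesian interrupted-time-series model
#'
#' The package's core fitting function.  Takes the pooled, weighted analysis
#' table (one row per person-interview, no missing cells in the model
#' columns), builds the ITS design (ethnicity-by-period level contrasts,
#' per-period time-since-interruption slopes, confounder adjustments, linear
#' secular trend, year and area random effects) and samples the posterior
#' with the in-package Gibbs sampler.  Rows are sorted internally by person
#' id and interview date before any random number is drawn, so row order
#' never affects the result.
#'
#' @param data pooled analysis table (see [build_design_matrix()]).
#' @param spec an [its_model_spec()].
#' @param seed integer seed.
#' @return an object of class `its_bayes` with methods `print`, `summary`,
#'   `coef`, `confint`, `fitted`, `residuals`, `plot` and [effect_table()].
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(its_sim_config(n_persons = 300, seed = 7))
#' prep <- apply_eligibility_filters(cohort$persons, cohort$observations)
#' rows <- attach_weights(prep$rows, mode = "unweighted")
#' fit <- its_bayes(rows, its_model_spec(chains = 2, iter = 400,
#'                                       warmup = 200, weighted = FALSE))
#' effect_table(fit)
#' }
#' @export
its_bayes <- function(data, spec = its_model_spec(), seed = 1L) {
  o <- order(data$person_id, as.Date(data$interview_date))
  data <- data[o, , drop = FALSE]
  design <- build_design_matrix(data, spec)
  fit_bayes_its(design, spec, seed)
}

#' @export
print.its_bayes <- function(x, ...) {
  cat("Bayesian interrupted time series linear model (Gibbs sampler)\n")
  cat(sprintf("  %d observations, %d fixed-effect columns, chains = %d\n",
              x$n, length(x$coef_names), x$spec$chains))
  cat(sprintf("  random effects: %s | weighted: %s | converged: %s\n",
              if (length(x$re_summary)) paste(names(x$re_summary),
                                              collapse = ", ") else "none",
              x$spec$weighted, x$converged))
  cat("\nEthnicity-by-period contrasts (GHQ-12 points, 95% CrI):\n")
  print(effect_table(x), ...)
  invisible(x)
}

#' @export
summary.its_bayes <- function(object, ...) object$summary

#' @export
coef.its_bayes <- function(object, ...) {
  stats::setNames(object$summary$mean[seq_along(object$coef_names)],
                  object$coef_names)
}

#' @export
confint.its_bayes <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- t(apply(object$draws[, object$coef_names, drop = FALSE], 2L,
               stats::quantile, c(a, 1 - a)))
  if (!missing(parm)) q <- q[parm, , drop = FALSE]
  q
}

#' @export
fitted.its_bayes <- function(object, ...) {
  d <- object$design
  eta <- drop(d$X %*% coef(object))
  for (r in names(d$re_index))
    eta <- eta + object$re_summary[[r]]$mean[d$re_index[[r]]]
  eta
}

#' @export
residuals.its_bayes <- function(object, ...) {
  object$design$y - fitted(object)
}

#' Plot posterior ethnicity-by-period contrasts
#'
#' Dot-and-interval plot of the mean differences and per-year slope contrasts
#' for each minoritised group relative to the reference, per exposure period.
#' @param x an `its_bayes` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.its_bayes <- function(x, ...) {
  et <- effect_table(x, format = FALSE)
  rows <- et[et$ethnicity != x$spec$reference_ethnicity, ]
  est <- c(rows$md_p2, rows$md_p3)
  lo <- c(rows$md_p2_lo, rows$md_p3_lo)
  hi <- c(rows$md_p2_hi, rows$md_p3_hi)
  lab <- c(paste(rows$ethnicity, "p2"), paste(rows$ethnicity, "p3"))
  k <- length(est)
  graphics::plot(est, seq_len(k), xlim = range(c(lo, hi, 0)),
                 yaxt = "n", xlab = "Mean difference in GHQ-12 (95% CrI)",
                 ylab = "", pch = 19, ...)
  graphics::segments(lo, seq_len(k), hi, seq_len(k))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.7)
  invisible(x)
}
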