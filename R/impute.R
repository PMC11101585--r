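#' Configuration for chained-equations imputation
#'
#' @param n_imputations number of completed datasets (the conventional 5 by
#'   default).
#' @param n_iterations chained sweeps per imputation (10 by default, the
#'   published analysis's setting; read as chain sweeps, and exposed
#'   separately from `n_imputations`).
#' @param seed integer RNG seed; imputations differ only via the RNG stream.
#' @param variables ordered covariate names eligible for imputation; only
#'   categorical covariates are imputable, and the outcome, sex and birth
#'   year are never imputed.
#' @param decay ridge (weight-decay) stabilisation for the multinomial
#'   conditionals, guarding sparse categories.
#' @return object of class `its_impute_config`.
#' @export
impute_config <- function(n_imputations = 5L, n_iterations = 10L, seed = 1L,
                          variables = maskable_covariates(), decay = 1e-3) {
  if (n_imputations < 1L) stop("n_imputations must be >= 1")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  structure(list(n_imputations = as.integer(n_imputations),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), variables = variables,
                 decay = decay),
            class = "its_impute_config")
}

# Draw one category per row from a fitted multinomial conditional.
draw_from_conditional <- function(fit, newdata, levels) {
  pr <- stats::predict(fit, newdata = newdata, type = "probs")
  if (is.null(dim(pr))) {            # binary conditional: P(second level)
    pr <- cbind(1 - pr, pr)
    colnames(pr) <- levels
  }
  pr <- pr[, levels, drop = FALSE]
  apply(pr, 1L, function(p) sample(levels, 1L, prob = pmax(p, 1e-12)))
}

#' Chained-equations multiple imputation of categorical covariates
#'
#' Per imputation: missing cells are initialised by sampling the observed
#' marginal of their variable; then `n_iterations` sweeps run in which each
#' variable with missingness is regressed (multinomial logistic with ridge
#' stabilisation, [nnet::multinom()]) on all other imputable covariates plus
#' sex and ethnicity, using the rows where it was observed, and its missing
#' cells are redrawn from the fitted conditional.  Only observed categories
#' can be imputed into.  Observed cells are never altered.
#'
#' @param rows analysis table with possibly missing categorical covariates.
#' @param config an [impute_config()].
#' @return object of class `its_imputations`: list with `imputations` (list
#'   of completed data.frames), `miss` (logical matrix of the originally
#'   missing cells) and `rows` (the input).
#' @export
chained_imputation <- function(rows, config = impute_config()) {
  vars <- intersect(config$variables, names(rows))
  miss <- vapply(vars, function(v) is.na(rows[[v]]), logical(nrow(rows)))
  if (nrow(rows) == 1L) miss <- matrix(miss, nrow = 1L,
                                       dimnames = list(NULL, vars))
  all_missing <- vars[colSums(miss) == nrow(rows)]
  if (length(all_missing))
    stop("variable(s) with 100% missingness cannot be imputed: ",
         paste(all_missing, collapse = ", "))
  anchors <- intersect(c("sex", "ethnicity"), names(rows))
  if (!length(anchors) && !length(vars[colSums(miss) == 0L]))
    stop("chained imputation needs at least one fully observed variable")
  to_impute <- vars[colSums(miss) > 0L]
  set.seed(config$seed)
  if (!length(to_impute)) {
    return(structure(list(imputations = replicate(config$n_imputations, rows,
                                                  simplify = FALSE),
                          miss = miss, rows = rows),
                     class = "its_imputations"))
  }

  levs <- lapply(vars, function(v) sort(unique(rows[[v]][!miss[, v]])))
  names(levs) <- vars

  imputations <- vector("list", config$n_imputations)
  for (m in seq_len(config$n_imputations)) {
    comp <- rows
    for (v in to_impute)
      comp[[v]][miss[, v]] <- sample(comp[[v]][!miss[, v]],
                                     sum(miss[, v]), replace = TRUE)
    for (it in seq_len(config$n_iterations)) {
      for (v in to_impute) {
        preds <- c(setdiff(vars, v), anchors)
        dat <- comp[c(v, preds)]
        for (p in c(v, preds)) dat[[p]] <- factor(dat[[p]])
        # constant predictors carry no information and break the contrasts
        preds <- preds[vapply(dat[preds], nlevels, 0L) > 1L]
        form <- stats::as.formula(
          paste(v, "~", if (length(preds)) paste(preds, collapse = "+")
                        else "1"))
        fit <- nnet::multinom(form, data = dat[!miss[, v], , drop = FALSE],
                              decay = config$decay, trace = FALSE,
                              maxit = 200, MaxNWts = 5000)
        comp[[v]][miss[, v]] <-
          draw_from_conditional(fit, dat[miss[, v], , drop = FALSE],
                                levs[[v]])
      }
    }
    imputations[[m]] <- comp
  }
  structure(list(imputations = imputations, miss = miss, rows = rows),
            class = "its_imputations")
}

#' Pool imputed datasets by per-cell mode
#'
#' Each originally missing cell takes the most frequent imputed category
#' across the completed datasets; ties are broken by the lowest category code
#' (the variable's first level in sorted order).  Observed cells are passed
#' through unaltered, and all downstream analyses run on this single pooled
#' dataset — the published analysis's combination rule, which deliberately
#' departs from Rubin's rules (not implemented here).
#'
#' @param imp an `its_imputations` object from [chained_imputation()], or a
#'   bare list of completed data.frames of identical shape (in which case no
#'   provenance is known and every cell is pooled as-is by mode).
#' @return the pooled data.frame with a `<var>_prov` column per imputable
#'   covariate ("observed" or "imputed").
#' @export
pool_by_mode <- function(imp) {
  if (!inherits(imp, "its_imputations")) {
    shapes <- vapply(imp, function(d) paste(dim(d), collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
      stop("shape mismatch across imputed datasets")
    miss <- NULL; imps <- imp; rows <- imp[[1L]]
    vars <- intersect(maskable_covariates(), names(rows))
  } else {
    imps <- imp$imputations; miss <- imp$miss; rows <- imp$rows
    vars <- colnames(miss)
  }
  pooled <- rows
  for (v in vars) {
    cells <- if (is.null(miss)) which(rep(TRUE, nrow(rows)))
             else which(miss[, v])
    if (length(cells)) {
      draws <- vapply(imps, function(d) d[[v]][cells],
                      character(length(cells)))
      if (length(cells) == 1L) draws <- matrix(draws, nrow = 1L)
      pooled[[v]][cells] <- apply(draws, 1L, function(x) {
        tab <- table(x)
        names(tab)[which.max(tab)]   # which.max: first max in sorted order
      })
    }
    pooled[[paste0(v, "_prov")]] <- "observed"
    if (!is.null(miss)) pooled[[paste0(v, "_prov")]][miss[, v]] <- "imputed"
  }
  pooled
}
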