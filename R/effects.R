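#' Summarise posterior ethnicity-by-period contrasts as an effect table
#'
#' Builds the headline results table: one row per ethnic group, with the
#' period-2 and period-3 mean differences (the ethnicity-by-period level
#' coefficients) and the per-year slope contrasts (the
#' ethnicity-by-time-since-period coefficients), each with its 95% credible
#' interval.  The reference group's row is rendered "Ref".
#'
#' @param fit an [its_bayes()] fit.
#' @param format if `TRUE`, return a character table with cells like
#'   `"0.67 (0.06 to 1.28)"`; otherwise (default) a numeric data.frame of
#'   class `its_effect_table` with point estimates and interval bounds.
#' @return data.frame; a missing interaction coefficient (e.g. dropped as
#'   constant) is an error naming the coefficient.
#' @export
effect_table <- function(fit, format = FALSE) {
  spec <- fit$spec
  s <- fit$summary
  grab <- function(name) {
    i <- match(name, s$parameter)
    if (is.na(i)) stop("coefficient missing from the posterior: ", name)
    c(est = s$mean[i], lo = s$q2.5[i], hi = s$q97.5[i])
  }
  groups <- c(setdiff(ethnic_groups(), spec$reference_ethnicity),
              spec$reference_ethnicity)
  out <- data.frame(ethnicity = groups,
                    n = NA_integer_,
                    md_p2 = NA_real_, md_p2_lo = NA_real_, md_p2_hi = NA_real_,
                    sl_p2 = NA_real_, sl_p2_lo = NA_real_, sl_p2_hi = NA_real_,
                    md_p3 = NA_real_, md_p3_lo = NA_real_, md_p3_hi = NA_real_,
                    sl_p3 = NA_real_, sl_p3_lo = NA_real_, sl_p3_hi = NA_real_)
  eth_cols <- intersect(paste0("eth:", groups), colnames(fit$design$X))
  eth_dummies <- fit$design$X[, eth_cols, drop = FALSE]
  for (k in seq_along(groups)) {
    g <- groups[k]
    cn <- paste0("eth:", g)
    out$n[k] <- if (cn %in% eth_cols) sum(eth_dummies[, cn])
                else sum(rowSums(eth_dummies) == 0)
  }
  for (k in seq_along(groups)) {
    g <- groups[k]
    if (g == spec$reference_ethnicity) next
    md2 <- grab(paste0("eth:", g, ":period:2"))
    md3 <- grab(paste0("eth:", g, ":period:3"))
    if (spec$slope_coding == "per-period") {
      sl2 <- grab(paste0("eth:", g, ":tsp:2"))
      sl3 <- grab(paste0("eth:", g, ":tsp:3"))
    } else {
      sl2 <- sl3 <- grab(paste0("eth:", g, ":tsp"))
    }
    out[k, 3:14] <- c(md2, sl2, md3, sl3)
  }
  class(out) <- c("its_effect_table", "data.frame")
  attr(out, "reference") <- spec$reference_ethnicity
  if (format) format(out) else out
}

#' @export
format.its_effect_table <- function(x, digits = 2, ...) {
  cell <- function(e, l, h)
    ifelse(is.na(e), "Ref",
           sprintf(paste0("%.", digits, "f (%.", digits, "f to %.",
                          digits, "f)"), e, l, h))
  data.frame(ethnicity = x$ethnicity,
             md_period2 = cell(x$md_p2, x$md_p2_lo, x$md_p2_hi),
             slope_period2 = cell(x$sl_p2, x$sl_p2_lo, x$sl_p2_hi),
             md_period3 = cell(x$md_p3, x$md_p3_lo, x$md_p3_hi),
             slope_period3 = cell(x$sl_p3, x$sl_p3_lo, x$sl_p3_hi))
}

#' @export
print.its_effect_table <- function(x, ...) {
  print(format(x), row.names = FALSE, ...)
  invisible(x)
}
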