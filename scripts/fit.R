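#!/usr/bin/env Rscript
# Fit the Bayesian ITS analysis on a cohort directory written by
# scripts/simulate.R (or any CSV pair with the same column dictionary) and
# write the effect tables as CSV.
#
# Usage: Rscript scripts/fit.R --data <dir> [--analyses main,stratify_uk_born,
#        stratify_income,sens_unweighted,sens_complete_case,sens_all_periods]
#        --seed <int> --out <dir>

suppressPackageStartupMessages(library(itsbayes))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
data_dir <- arg_val("--data")
analyses <- strsplit(arg_val("--analyses", "main"), ",")[[1L]]
seed <- as.integer(arg_val("--seed", "1"))
out <- arg_val("--out", "fits")
if (is.null(data_dir)) stop("--data <dir> is required")
if (!dir.exists(out)) dir.create(out, recursive = TRUE)

coh <- read_cohort(data_dir)
main <- run_main(coh, seed = seed)
write.csv(main$exclusions, file.path(out, "exclusion_log.csv"),
          row.names = FALSE)
write.csv(main$weights, file.path(out, "weight_table.csv"), row.names = FALSE)

save_effects <- function(effects, name) {
  write.csv(format(effects), file.path(out, paste0(name, ".csv")),
            row.names = FALSE)
  cat("==", name, "==\n")
  print(effects)
}
if ("main" %in% analyses) save_effects(main$effects, "effects_main")
for (strat in c(uk_born = "stratify_uk_born", income = "stratify_income")) {
  if (strat %in% analyses) {
    res <- run_stratified(main, names(which(strat == c(
      uk_born = "stratify_uk_born", income = "stratify_income"))), seed = seed)
    for (s in names(res))
      save_effects(res[[s]]$effects, paste0("effects_", s))
  }
}
for (sens in c("unweighted", "complete_case", "all_periods")) {
  if (paste0("sens_", sens) %in% analyses) {
    res <- run_sensitivity(coh, sens, seed = seed)
    save_effects(res$effects, paste0("effects_sens_", sens))
  }
}
desc <- make_descriptive_table(main$pooled)
write.csv(desc$characteristics, file.path(out, "descriptive.csv"),
          row.names = FALSE)
cat("outputs in", out, "\n")
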