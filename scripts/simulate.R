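#!/usr/bin/env Rscript
# Generate a synthetic cohort and write it (with its truth sidecar) to a
# directory.
#
# Usage: Rscript scripts/simulate.R [--config <yaml>] --seed <int> --out <dir>

suppressPackageStartupMessages(library(itsbayes))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}
config_path <- arg_val("--config")
seed <- arg_val("--seed")
out <- arg_val("--out", "cohort")

cfg <- if (is.null(config_path)) its_sim_config() else
  sim_config_from_yaml(config_path)
if (!is.null(seed)) cfg$seed <- as.integer(seed)

coh <- simulate_cohort(cfg)
coh$observations <- inject_missingness(coh$observations, cfg)
write_cohort(coh, out)
cat("wrote", nrow(coh$persons), "persons and", nrow(coh$observations),
    "interviews to", out, "\n")
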