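#' Write a cohort to disk (long-format CSV plus a truth sidecar)
#'
#' Writes `persons.csv`, `observations.csv` (one row per person-interview,
#' missing values as empty fields) and `truth.yaml` (the flat key-value map
#' of every planted parameter for the run).
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$persons, file.path(dir, "persons.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$truth))
    yaml::write_yaml(cohort$truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `persons.csv` and `observations.csv`.
#' @return list with `persons`, `observations` and (if present) `truth`.
#' @export
read_cohort <- function(dir) {
  persons <- utils::read.csv(file.path(dir, "persons.csv"),
                             na.strings = "", stringsAsFactors = FALSE)
  obs <- utils::read.csv(file.path(dir, "observations.csv"),
                         na.strings = "", stringsAsFactors = FALSE)
  obs$interview_date <- as.Date(obs$interview_date)
  for (v in intersect(maskable_covariates(), names(obs)))
    obs[[v]] <- as.character(obs[[v]])
  truth_path <- file.path(dir, "truth.yaml")
  truth <- if (file.exists(truth_path)) yaml::read_yaml(truth_path) else NULL
  list(persons = persons, observations = obs, truth = truth)
}

#' Build a simulation config from a YAML file
#'
#' Reads a YAML mapping whose keys are arguments of [its_sim_config()]
#' (matrix-valued fields given as lists of rows) and returns the validated
#' config; omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return an `its_sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("true_level_effects", "true_slope_effects"))
    if (!is.null(raw[[f]]))
      raw[[f]] <- do.call(rbind, raw[[f]])
  if (!is.null(raw$response_prob))
    raw$response_prob <- do.call(rbind, raw$response_prob)
  if (!is.null(raw$wave_windows))
    raw$wave_windows <- data.frame(
      wave = seq_along(raw$wave_windows),
      start = as.Date(vapply(raw$wave_windows, `[[`, "", 1L)),
      end = as.Date(vapply(raw$wave_windows, `[[`, "", 2L)))
  do.call(its_sim_config, raw)
}
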