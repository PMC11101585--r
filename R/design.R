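#' Default exposure-period definitions
#'
#' Three closed date intervals partitioning the study range
#' \[2009-08-01, 2020-03-23\]:
#' period 1 before the Immigration Act 2014 (Aug 1, 2009 - May 13, 2014),
#' period 2 after the Act and before the Windrush-scandal media coverage
#' (May 14, 2014 - Nov 27, 2017), and period 3 after media coverage began and
#' before the first COVID-19 lockdown (Nov 28, 2017 - Mar 23, 2020).
#' Both endpoints of each interval are inclusive.
#'
#' @param starts,ends `Date` (or ISO-8601 character) vectors of equal length
#'   overriding the defaults; intervals must be chronological, non-overlapping
#'   and gap-free.
#' @return data.frame with columns `index`, `start_date`, `end_date`, `label`.
#' @export
exposure_periods <- function(
    starts = c("2009-08-01", "2014-05-14", "2017-11-28"),
    ends   = c("2014-05-13", "2017-11-27", "2020-03-23")) {
  starts <- as.Date(starts); ends <- as.Date(ends)
  if (length(starts) != length(ends) || length(starts) < 1L)
    stop("starts and ends must be non-empty and of equal length")
  if (any(is.na(starts)) || any(is.na(ends))) stop("malformed period date")
  if (any(ends < starts)) stop("period end precedes its start")
  if (length(starts) > 1L &&
      any(starts[-1L] != ends[-length(ends)] + 1L))
    stop("periods must partition the study range with no gaps or overlaps")
  data.frame(index = seq_along(starts), start_date = starts, end_date = ends,
             label = paste("period", seq_along(starts)))
}

#' Assign interviews to exposure periods from exact dates
#'
#' @param interview_date `Date` (or ISO-8601 character) vector.
#' @param periods period table from [exposure_periods()].
#' @return integer vector: the containing period's index, or `NA` for dates
#'   outside the study range ("ineligible").
#' @examples
#' assign_exposure_period(as.Date(c("2014-05-13", "2014-05-14")))  # 1, 2
#' @export
assign_exposure_period <- function(interview_date, periods = exposure_periods()) {
  d <- as.Date(interview_date)
  if (anyNA(d) != anyNA(interview_date)) stop("malformed interview date")
  idx <- rep(NA_integer_, length(d))
  for (k in seq_len(nrow(periods))) {
    inside <- !is.na(d) & d >= periods$start_date[k] & d <= periods$end_date[k]
    idx[inside] <- periods$index[k]
  }
  idx
}

#' Compute the model's time covariates
#'
#' `calendar_time` is years since the study start (the first period's start
#' date) and `time_since_period` is years since the start of the row's
#' exposure period, both using a 365.25-day year.
#'
#' @param rows data.frame with `interview_date` and `period` columns.
#' @param periods period table from [exposure_periods()].
#' @return `rows` with `calendar_time` and `time_since_period` filled.
#' @export
compute_time_covariates <- function(rows, periods = exposure_periods()) {
  d <- as.Date(rows$interview_date)
  origin <- periods$start_date[1L]
  rows$calendar_time <- as.numeric(d - origin) / 365.25
  pstart <- periods$start_date[match(rows$period, periods$index)]
  rows$time_since_period <- as.numeric(d - pstart) / 365.25
  rows
}

#' Ethnic groups in scope
#'
#' The comparison group (White) and the five minoritised groups considered
#' exposed to the hostile environment policy, ordered with the reference
#' first.
#' @return character vector of length 6.
#' @export
ethnic_groups <- function() {
  c("White", "Black African", "Black Caribbean", "Indian", "Pakistani",
    "Bangladeshi")
}

#' Apply the eligibility filters and build the analysis table
#'
#' Filters, applied in this fixed order (so the exclusion log is
#' deterministic):
#' \enumerate{
#'   \item observations dated outside the exposure-period range;
#'   \item observations where the participant is under 16 (age = interview
#'     year minus birth year);
#'   \item observations without a complete GHQ-12 outcome (and, as a
#'     consequence, persons with no complete outcome in any wave);
#'   \item persons with missing sex or year of birth;
#'   \item persons outside the six in-scope ethnic groups.
#' }
#' Rows surviving every filter get period assignment and time covariates.
#' A person interviewed more than once within one exposure period keeps all
#' rows by default; `first_per_period = TRUE` keeps only the earliest.
#'
#' @param persons data.frame of person-level attributes (`person_id`,
#'   `ethnicity`, `stratum`, `area`, `birth_year`, `sex`, ...).
#' @param observations data.frame of interviews (`person_id`, `wave`,
#'   `interview_date`, `ghq1`..`ghq12` and/or `ghq_total`, covariates).
#' @param periods period table from [exposure_periods()].
#' @param first_per_period keep only the earliest interview per person and
#'   exposure period.
#' @return list with `rows` (the analysis table: one row per retained
#'   person-interview, person attributes joined, `period`, `ghq_total`,
#'   `calendar_time`, `time_since_period` filled) and `log` (the exclusion
#'   log: one row per filter with observation/person counts).
#' @export
apply_eligibility_filters <- function(persons, observations,
                                      periods = exposure_periods(),
                                      first_per_period = FALSE) {
  obs <- add_ghq_scores(observations)
  obs$period <- assign_exposure_period(obs$interview_date, periods)

  pcols <- setdiff(names(persons), names(obs))
  obs <- cbind(obs, persons[match(obs$person_id, persons$person_id),
                            pcols, drop = FALSE])

  log <- data.frame(step = character(), unit = character(),
                    removed = integer(), observations_left = integer(),
                    persons_left = integer())
  note <- function(step, unit, removed, obs) {
    rbind(log, data.frame(step = step, unit = unit, removed = removed,
                          observations_left = nrow(obs),
                          persons_left = length(unique(obs$person_id))))
  }

  keep <- !is.na(obs$period)
  log <- note("outside exposure periods", "observations", sum(!keep),
              obs[keep, ])
  obs <- obs[keep, , drop = FALSE]

  age <- as.integer(format(as.Date(obs$interview_date), "%Y")) - obs$birth_year
  keep <- is.na(age) | age >= 16L   # missing birth year handled at step 4
  log <- note("aged under 16 at interview", "observations", sum(!keep),
              obs[keep, ])
  obs <- obs[keep, , drop = FALSE]

  keep <- !is.na(obs$ghq_total)
  log <- note("incomplete GHQ-12 outcome", "observations", sum(!keep),
              obs[keep, ])
  obs <- obs[keep, , drop = FALSE]

  bad_person <- is.na(obs$sex) | is.na(obs$birth_year)
  drop_ids <- unique(obs$person_id[bad_person])
  keep <- !(obs$person_id %in% drop_ids)
  log <- note("missing sex or year of birth", "persons", length(drop_ids),
              obs[keep, ])
  obs <- obs[keep, , drop = FALSE]

  out_of_scope <- is.na(obs$ethnicity) | !(obs$ethnicity %in% ethnic_groups())
  drop_ids <- unique(obs$person_id[out_of_scope])
  keep <- !(obs$person_id %in% drop_ids)
  log <- note("ethnicity outside the six in-scope groups", "persons",
              length(drop_ids), obs[keep, ])
  obs <- obs[keep, , drop = FALSE]

  if (first_per_period && nrow(obs)) {
    o <- order(obs$person_id, obs$period, as.Date(obs$interview_date))
    obs <- obs[o, , drop = FALSE]
    obs <- obs[!duplicated(obs[c("person_id", "period")]), , drop = FALSE]
  }

  obs <- compute_time_covariates(obs, periods)
  obs$age <- as.integer(format(as.Date(obs$interview_date), "%Y")) -
    obs$birth_year
  rownames(obs) <- NULL
  list(rows = obs, log = log)
}
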