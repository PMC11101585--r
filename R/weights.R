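#' Estimate response probabilities and inverse-probability weights
#'
#' Builds the bespoke longitudinal weight table: within each sampling stratum
#' and exposure period, the response probability is the fraction of the
#' included cohort's persons in that stratum who contributed at least one
#' eligible interview in that period, and the weight is its reciprocal
#' (Horvitz-Thompson).  Probabilities are empirical cell proportions — no
#' model smoothing and no trimming; extreme weights signal a configuration
#' problem and are visible in the emitted table.
#'
#' @param persons data.frame of the included cohort with `person_id` and
#'   `stratum` (the eligibility base: persons with at least one complete
#'   outcome anywhere in the study).
#' @param rows analysis rows with `person_id`, `stratum`, `period`.
#' @param periods integer vector of period indices to tabulate.
#' @return data.frame (class `its_weight_table`) with columns `stratum`,
#'   `period`, `eligible`, `responders`, `probability`, `weight`.  Cells with
#'   no eligible persons are absent; a cell with eligible persons but no
#'   responders is an error ("empty response cell").
#' @export
estimate_response_probabilities <- function(persons, rows, periods = 1:3) {
  if (!all(rows$person_id %in% persons$person_id))
    stop("every responder must be an eligible person")
  strata <- sort(unique(persons$stratum))
  grid <- expand.grid(stratum = strata, period = periods)
  eligible <- as.vector(table(factor(persons$stratum, levels = strata)))
  grid$eligible <- eligible[match(grid$stratum, strata)]
  key <- function(s, p) paste(s, p, sep = ":")
  resp <- unique(rows[c("person_id", "stratum", "period")])
  resp_n <- table(key(resp$stratum, resp$period))
  grid$responders <- as.integer(resp_n[key(grid$stratum, grid$period)])
  grid$responders[is.na(grid$responders)] <- 0L
  grid <- grid[grid$eligible > 0L, , drop = FALSE]
  if (any(grid$responders == 0L))
    stop("empty response cell: eligible persons but no responders in ",
         paste(key(grid$stratum, grid$period)[grid$responders == 0L],
               collapse = ", "))
  grid$probability <- grid$responders / grid$eligible
  grid$weight <- 1 / grid$probability
  rownames(grid) <- NULL
  class(grid) <- c("its_weight_table", "data.frame")
  grid
}

#' Attach inverse-probability weights to analysis rows
#'
#' @param rows analysis rows with `stratum` and `period`.
#' @param table weight table from [estimate_response_probabilities()]
#'   (required when `mode = "weighted"`).
#' @param mode `"weighted"` (look up the row's stratum-by-period cell) or
#'   `"unweighted"` (all weights 1, the weighting sensitivity analysis).
#' @return `rows` with a `weight` column.
#' @export
attach_weights <- function(rows, table = NULL,
                           mode = c("weighted", "unweighted")) {
  mode <- match.arg(mode)
  if (mode == "unweighted") {
    rows$weight <- 1
    return(rows)
  }
  if (is.null(table)) stop("weighted mode requires a weight table")
  i <- match(paste(rows$stratum, rows$period),
             paste(table$stratum, table$period))
  if (anyNA(i))
    stop("configuration error: no weight-table cell for stratum:period ",
         paste(unique(paste(rows$stratum, rows$period, sep = ":")[is.na(i)]),
               collapse = ", "))
  rows$weight <- table$weight[i]
  rows
}
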