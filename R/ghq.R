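#' Score the 12-item General Health Questionnaire (Likert 0-3)
#'
#' Sums the twelve item responses into the continuous 0-36 distress total.
#' Likert scoring (0-1-2-3) is used, not the binary screening scoring
#' (0-0-1-1): only Likert scoring yields the 0-36 range used as the
#' continuous outcome.  There is no partial-response proration: a response
#' with any absent item is incomplete and the corresponding interview is
#' ineligible as an outcome measurement.
#'
#' @param items integer vector of length 12 (a single response) or a numeric
#'   matrix / data.frame with 12 columns (one response per row); each present
#'   value must be in \{0, 1, 2, 3\}, `NA` marks an absent item.
#' @param strict if `TRUE` (default), any absent item signals an
#'   "incomplete outcome" error; if `FALSE`, incomplete responses score `NA`
#'   (used by the eligibility filters, which drop such interviews and count
#'   them in the exclusion log).
#' @return integer total in \[0, 36\] (scalar for a vector input, vector for
#'   a matrix input), `NA` for incomplete responses when `strict = FALSE`.
#' @examples
#' score_ghq12(rep(3L, 12))          # 36, the scale maximum
#' score_ghq12(rep(0L, 12))          # 0, the scale minimum
#' score_ghq12(c(3,2,1,0,3,2,1,0,3,2,1,0))  # 18
#' @export
score_ghq12 <- function(items, strict = TRUE) {
  if (is.data.frame(items)) items <- as.matrix(items)
  single <- !is.matrix(items)
  if (single) items <- matrix(items, nrow = 1L)
  if (ncol(items) != 12L)
    stop("a GHQ-12 response has exactly 12 items, got ", ncol(items))
  ok <- is.na(items) | (items %in% 0:3)
  if (!all(ok))
    stop("GHQ-12 item values must be in {0,1,2,3} or NA")
  incomplete <- rowSums(is.na(items)) > 0L
  if (strict && any(incomplete))
    stop("incomplete outcome: ", sum(incomplete),
         " response(s) with absent GHQ-12 items")
  total <- as.integer(rowSums(items))
  total[incomplete] <- NA_integer_
  if (single) total[[1L]] else total
}

#' Attach GHQ-12 totals to an observation table
#'
#' Computes the 0-36 total from the twelve item columns `ghq1`..`ghq12`
#' and/or validates a precomputed `ghq_total` column.  When both items and a
#' precomputed total are present and disagree, the record is flagged and
#' rejected (its total is set to `NA` so the eligibility filters remove it).
#'
#' @param observations data.frame of interviews with columns `ghq1`..`ghq12`
#'   and/or `ghq_total`.
#' @return `observations` with a `ghq_total` column (NA where incomplete or
#'   inconsistent) and a logical `ghq_conflict` column.
#' @export
add_ghq_scores <- function(observations) {
  item_cols <- paste0("ghq", 1:12)
  has_items <- all(item_cols %in% names(observations))
  has_total <- "ghq_total" %in% names(observations)
  if (!has_items && !has_total)
    stop("observations carry neither ghq1..ghq12 items nor ghq_total")
  conflict <- rep(FALSE, nrow(observations))
  if (has_items) {
    scored <- score_ghq12(observations[item_cols], strict = FALSE)
    if (has_total) {
      both <- !is.na(scored) & !is.na(observations$ghq_total)
      conflict <- both & scored != observations$ghq_total
      total <- ifelse(conflict, NA_integer_, scored)
      # keep a supplied total where items are absent
      total[is.na(scored) & !conflict] <-
        observations$ghq_total[is.na(scored) & !conflict]
    } else {
      total <- scored
    }
  } else {
    total <- observations$ghq_total
    bad <- !is.na(total) & (total < 0 | total > 36)
    if (any(bad)) stop("ghq_total outside [0, 36]")
  }
  observations$ghq_total <- as.integer(total)
  observations$ghq_conflict <- conflict
  observations
}
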