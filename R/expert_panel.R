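# Expert competency model: a 100-point score over four dimensions with caps
# background 10, know-how 20, anchored behavior 60, engagement 10. The total
# doubles as the expert's rating weight W_i; experts enter the panel only when
# the total is strictly above the threshold (default 50).

COMPETENCY_CAPS <- c(background = 10, knowhow = 20,
                     anchored_behavior = 60, engagement = 10)

#' Expert competency score
#'
#' Sums the four competency sub-scores (background out of 10, know-how and
#' skill set out of 20, anchored behavior -- familiarity with the standard
#' framework -- out of 60, and survey engagement out of 10) into a 100-point
#' competency score.
#'
#' @param profile list or one-row data frame with numeric fields `background`,
#'   `knowhow`, `anchored_behavior`, `engagement`.
#' @return the total competency score in [0, 100].
#' @export
competency_score <- function(profile) {
  for (dim in names(COMPETENCY_CAPS)) {
    v <- profile[[dim]]
    if (is.null(v) || is.na(v)) {
      stop("missing competency sub-score: ", dim, call. = FALSE)
    }
    if (v < 0 || v > COMPETENCY_CAPS[[dim]]) {
      stop("sub-score out of range for dimension '", dim, "': ", v,
           " (cap ", COMPETENCY_CAPS[[dim]], ")", call. = FALSE)
    }
  }
  profile$background + profile$knowhow + profile$anchored_behavior +
    profile$engagement
}

#' Select the expert panel by competency threshold
#'
#' An expert is included iff their competency score is strictly greater than
#' the threshold; included scores are recorded as the rating weights W_i.
#'
#' @param profiles data frame of expert profiles with columns `expert_id`,
#'   `background`, `knowhow`, `anchored_behavior`, `engagement`.
#' @param threshold inclusion threshold (default 50, strict).
#' @return list with `included` (tibble of `expert_id`, `weight`), `excluded`
#'   (character ids) and `threshold`.
#' @export
select_panel <- function(profiles, threshold = 50) {
  profiles <- tibble::as_tibble(profiles)
  if (nrow(profiles) == 0) {
    return(list(included = tibble::tibble(expert_id = character(),
                                          weight = numeric()),
                excluded = character(), threshold = threshold))
  }
  scores <- vapply(seq_len(nrow(profiles)),
                   function(i) competency_score(profiles[i, ]), numeric(1))
  keep <- scores > threshold
  list(
    included = tibble::tibble(expert_id = as.character(profiles$expert_id[keep]),
                              weight = scores[keep]),
    excluded = as.character(profiles$expert_id[!keep]),
    threshold = threshold
  )
}

#' Survey response rate
#'
#' The willingness index of participants: returned questionnaires over
#' distributed questionnaires, as a percentage. Rates not strictly above 70%
#' are flagged as questionable.
#'
#' @param n_feedback number of questionnaires returned.
#' @param n_distributed number of questionnaires distributed (> 0).
#' @return list with `rate` (percentage) and `flagged` (TRUE when the rate is
#'   not strictly over 70%).
#' @export
response_rate <- function(n_feedback, n_distributed) {
  if (n_distributed <= 0) stop("n_distributed must be positive", call. = FALSE)
  if (n_feedback < 0 || n_feedback > n_distributed) {
    stop("n_feedback must lie in [0, n_distributed]", call. = FALSE)
  }
  rate <- 100 * n_feedback / n_distributed
  list(rate = rate, flagged = !(rate > 70))
}
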