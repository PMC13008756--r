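# Per-indicator Delphi consensus statistics and the screening rule.
#
# Ratings are integers on a 10-point importance scale; a rating of 0 is a
# deletion vote, tallied separately and excluded from the importance
# statistics (mean, weighted mean, full-mark rate, CV).

#' Mean importance rating
#'
#' @param values integer ratings in 1..10.
#' @return arithmetic mean M_j.
#' @export
mean_rating <- function(values) {
  if (length(values) == 0) stop("no ratings", call. = FALSE)
  mean(values)
}

#' Competency-weighted mean rating
#'
#' Each expert's rating is weighted by their competency score W_i:
#' sum(W_i * C_ij) / sum(W_i). With equal weights this reduces to the
#' arithmetic mean.
#'
#' @param values ratings.
#' @param weights matching competency scores (non-negative, positive sum).
#' @return weighted mean X-bar_j.
#' @export
weighted_mean_rating <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights differ in length", call. = FALSE)
  }
  if (length(values) == 0) stop("no ratings", call. = FALSE)
  if (any(weights < 0)) stop("negative weight", call. = FALSE)
  sw <- sum(weights)
  if (sw <= 0) stop("weights sum to zero", call. = FALSE)
  sum(weights * values) / sw
}

#' Full-mark rate
#'
#' Fraction of experts awarding the maximum rating (10): a concentration
#' measure of expert opinion.
#'
#' @param values ratings.
#' @return K_j in [0, 1].
#' @export
full_mark_rate <- function(values) {
  if (length(values) == 0) stop("no ratings", call. = FALSE)
  mean(values == 10)
}

#' Coefficient of variation of an indicator's ratings
#'
#' Sample standard deviation (n - 1 denominator) divided by the indicator's
#' weighted mean -- the dispersion measure the screening rule compares against
#' its threshold (lower CV, better expert coordination).
#'
#' @param values ratings (n >= 2).
#' @param center the weighted mean X-bar_j (> 0).
#' @return V_j >= 0.
#' @export
coefficient_of_variation <- function(values, center) {
  if (length(values) < 2) stop("need at least two ratings", call. = FALSE)
  if (!is.finite(center) || center <= 0) {
    stop("center must be positive", call. = FALSE)
  }
  sd(values) / center
}

#' Screen an indicator on importance and dispersion
#'
#' Retain iff the weighted mean importance is at least the mean threshold
#' (default 7) and the coefficient of variation is strictly below the CV
#' threshold (default 0.25); otherwise exclude, recording which criterion
#' failed.
#'
#' @param weighted_mean X-bar_j.
#' @param cv V_j.
#' @param thresholds list with `mean` and `cv`.
#' @return list with `decision` ("retain"/"exclude") and `reason` (empty when
#'   retained; otherwise "low-importance", "high-dispersion" or both).
#' @export
screen_indicator <- function(weighted_mean, cv,
                             thresholds = list(mean = 7, cv = 0.25)) {
  reason <- character()
  if (weighted_mean < thresholds$mean) reason <- c(reason, "low-importance")
  if (cv >= thresholds$cv) reason <- c(reason, "high-dispersion")
  list(decision = if (length(reason) == 0) "retain" else "exclude",
       reason = reason)
}

#' Kendall's coefficient of concordance with tie correction
#'
#' Measures agreement among b experts ranking k indicators. Each expert's
#' ratings are converted to mid-ranks (ties share the average rank); with rank
#' sums R_j per indicator and per-expert tie terms T_i = sum over tie groups of
#' (t^3 - t),
#'
#'   W = (12 * sum(R_j^2) - 3 b^2 k (k+1)^2) /
#'       (b^2 k (k^2 - 1) - b * sum_i T_i)
#'
#' Significance uses the chi-square approximation chi2 = b (k - 1) W on k - 1
#' degrees of freedom (upper tail).
#'
#' @param ratings b x k numeric matrix (experts in rows, indicators in
#'   columns), no missing cells.
#' @return list with `w`, `chi2`, `df`, `p`, `b`, `k`, `rank_sums`.
#' @export
kendalls_w <- function(ratings) {
  ratings <- as.matrix(ratings)
  b <- nrow(ratings)
  k <- ncol(ratings)
  if (b < 2 || k < 2) stop("need at least 2 experts and 2 indicators",
                           call. = FALSE)
  if (any(!is.finite(ratings))) stop("missing cells in rating matrix",
                                     call. = FALSE)
  rk <- t(apply(ratings, 1, rank))  # mid-ranks within each expert
  R <- colSums(rk)
  tie_term <- sum(apply(ratings, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  }))
  num <- 12 * sum(R^2) - 3 * b^2 * k * (k + 1)^2
  den <- b^2 * k * (k^2 - 1) - b * tie_term
  if (den <= 0) {
    stop("degenerate rank variance: every expert rated all indicators ",
         "identically; W is undefined", call. = FALSE)
  }
  w <- num / den
  w <- min(max(w, 0), 1)  # guard tiny negative round-off
  chi2 <- b * (k - 1) * w
  df <- k - 1
  list(w = w, chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       b = b, k = k, rank_sums = R)
}

#' Compute a Delphi round's per-indicator statistics and panel consensus
#'
#' For every active indicator: deletion votes (rating 0) are counted and
#' excluded, then the mean, competency-weighted mean, full-mark rate and CV
#' are computed over the remaining ratings and the screening rule applied.
#' Kendall's W is computed over the complete expert-by-indicator block of raw
#' ratings.
#'
#' @param ratings long-form rating table: columns `expert_id`, `indicator_id`,
#'   `round`, `rating`.
#' @param panel a panel from [select_panel()].
#' @param tree the round's `indicator_tree`.
#' @param round which round to analyse.
#' @param thresholds screening thresholds, see [screen_indicator()].
#' @return list with `stats` (tibble, one row per active indicator) and
#'   `consensus` (see [kendalls_w()]).
#' @export
compute_round_stats <- function(ratings, panel, tree, round = 1L,
                                thresholds = list(mean = 7, cv = 0.25)) {
  ratings <- tibble::as_tibble(ratings)
  ratings <- ratings[ratings$round == round, , drop = FALSE]
  if (nrow(ratings) == 0) stop("no ratings for round ", round, call. = FALSE)
  act <- active_indicators(tree)

  alien <- setdiff(unique(ratings$expert_id), panel$included$expert_id)
  if (length(alien) > 0) {
    stop("ratings from expert(s) outside the panel: ",
         paste(alien, collapse = ", "), call. = FALSE)
  }
  stray <- setdiff(unique(ratings$indicator_id), act$id)
  if (length(stray) > 0) {
    stop("ratings for inactive or unknown indicator(s): ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(ratings[, c("expert_id", "indicator_id")])
  if (any(dup)) {
    stop("duplicate (expert, indicator) rating(s) within the round",
         call. = FALSE)
  }
  if (any(ratings$rating < 0 | ratings$rating > 10)) {
    stop("ratings must lie in 0..10", call. = FALSE)
  }

  wtab <- setNames(panel$included$weight, panel$included$expert_id)
  rows <- lapply(act$id, function(id) {
    rr <- ratings[ratings$indicator_id == id, , drop = FALSE]
    del <- sum(rr$rating == 0)
    rr <- rr[rr$rating > 0, , drop = FALSE]
    n <- nrow(rr)
    if (n == 0) {
      return(tibble::tibble(
        indicator_id = id, n_raters = 0L, deletion_votes = del,
        mean = NA_real_, weighted_mean = NA_real_, full_mark_rate = NA_real_,
        cv = NA_real_, decision = "exclude", reason = "all-deletion-votes"))
    }
    m <- mean_rating(rr$rating)
    xbar <- weighted_mean_rating(rr$rating, wtab[rr$expert_id])
    k <- full_mark_rate(rr$rating)
    v <- if (n >= 2) coefficient_of_variation(rr$rating, xbar) else 0
    scr <- screen_indicator(xbar, v, thresholds)
    tibble::tibble(indicator_id = id, n_raters = n, deletion_votes = del,
                   mean = m, weighted_mean = xbar, full_mark_rate = k, cv = v,
                   decision = scr$decision,
                   reason = paste(scr$reason, collapse = "+"))
  })
  stats <- do.call(rbind, rows)

  # consensus over the complete expert x indicator block of raw ratings
  experts <- sort(unique(ratings$expert_id))
  mat <- matrix(NA_real_, length(experts), nrow(act),
                dimnames = list(experts, act$id))
  mat[cbind(match(ratings$expert_id, experts),
            match(ratings$indicator_id, act$id))] <- ratings$rating
  if (any(is.na(mat))) {
    stop("incomplete rating block: every panel expert must rate every ",
         "active indicator in a round", call. = FALSE)
  }
  # W is undefined when every expert's ratings are constant (zero rank
  # variance); the per-indicator statistics are still valid, so record the
  # diagnostic instead of failing the round.
  consensus <- tryCatch(kendalls_w(mat), error = function(e) {
    list(w = NA_real_, chi2 = NA_real_, df = ncol(mat) - 1L, p = NA_real_,
         b = nrow(mat), k = ncol(mat), rank_sums = colSums(mat) * NA_real_,
         degenerate = conditionMessage(e))
  })

  list(stats = stats, consensus = consensus, round = round)
}
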