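# Round orchestration: run a Delphi round, apply expert-comment revisions,
# finalize the weighted evaluation system and score the framework to a QI.
# A round never mutates its input tree; every stage returns new objects.

#' Run one Delphi round
#'
#' Computes the per-indicator consensus statistics and panel-level Kendall's W,
#' applies the importance/dispersion screening, and derives the deletion flags
#' implied by the cascade rule (a second-layer indicator whose third-layer
#' children all fail screening is flagged for deletion, and recursively for the
#' first layer).
#'
#' @param tree the round's `indicator_tree`.
#' @param ratings long-form rating table for the round.
#' @param panel a panel from [select_panel()].
#' @param round round number.
#' @param thresholds screening thresholds.
#' @return list of class `delphi_round_result`: `round`, `stats`, `consensus`,
#'   `excluded` (ids failing screening), `cascade_deleted` (upper-layer ids
#'   flagged by the cascade), and `tree` (the input tree, unchanged).
#' @export
run_round <- function(tree, ratings, panel, round = 1L,
                      thresholds = list(mean = 7, cv = 0.25)) {
  res <- compute_round_stats(ratings, panel, tree, round, thresholds)
  excluded <- res$stats$indicator_id[res$stats$decision == "exclude"]

  # cascade: flag upper-layer indicators whose active children are all gone
  act <- active_indicators(tree)
  gone <- excluded
  cascade <- character()
  for (layer in c(2L, 1L)) {
    for (id in act$id[act$layer == layer]) {
      kids <- act$id[act$parent_id %in% id]
      if (length(kids) > 0 && all(kids %in% gone)) {
        cascade <- c(cascade, id)
        gone <- c(gone, id)
      }
    }
  }

  structure(list(round = round, stats = res$stats, consensus = res$consensus,
                 excluded = excluded, cascade_deleted = cascade, tree = tree),
            class = "delphi_round_result")
}

#' Apply between-round revisions to the indicator tree
#'
#' Applies screening exclusions and expert-comment deletions via
#' [prune_and_extend()] (with both cascade directions), appends additions, and
#' applies wording relabels. The result is the tree for the next round.
#'
#' @param tree an `indicator_tree`.
#' @param round_result a `delphi_round_result`, or NULL to apply manual
#'   revisions only.
#' @param additions data frame of new indicators (or NULL).
#' @param deletions character vector of extra ids to delete.
#' @param relabels data frame of wording changes (or NULL), see
#'   [relabel_indicators()].
#' @param round_tag tag for the revised tree.
#' @return a new `indicator_tree`.
#' @export
apply_revisions <- function(tree, round_result = NULL, additions = NULL,
                            deletions = character(), relabels = NULL,
                            round_tag = tree$round_tag) {
  del <- deletions
  if (!is.null(round_result)) del <- union(del, round_result$excluded)
  out <- prune_and_extend(tree, deletions = del, additions = additions)
  if (!is.null(relabels) && nrow(relabels) > 0) {
    out <- relabel_indicators(out, relabels)
  }
  out$round_tag <- round_tag
  out
}

#' Finalize the weighted evaluation system
#'
#' After the last Delphi round retains every active indicator, the weighted
#' means of that round set the normalised weights at every layer, producing
#' the evaluation system used for assessment.
#'
#' @param tree the final `indicator_tree`.
#' @param round_result the last round's `delphi_round_result`; every active
#'   indicator must have been retained.
#' @return list of class `evaluation_system` with `tree` (weights set) and
#'   `provenance` (round number).
#' @export
finalize_system <- function(tree, round_result) {
  act <- active_indicators(tree)
  st <- round_result$stats
  still_excluded <- intersect(act$id,
                              st$indicator_id[st$decision == "exclude"])
  if (length(still_excluded) > 0) {
    stop("excluded indicator(s) still active in the tree: ",
         paste(still_excluded, collapse = ", "), call. = FALSE)
  }
  wm <- setNames(st$weighted_mean, st$indicator_id)
  weighted <- normalize_weights(tree, wm)
  structure(list(tree = weighted, provenance = round_result$round),
            class = "evaluation_system")
}

#' Score the framework with the finalized evaluation system
#'
#' Final third-layer scores are the competency-weighted means of the
#' assessment ratings (importance scale 1..10; deletion votes are not allowed
#' at the assessment stage); upper-layer scores and the quality index come
#' from [aggregate_scores()].
#'
#' @param system an `evaluation_system`.
#' @param ratings long-form assessment rating table covering every active leaf
#'   indicator.
#' @param panel a panel from [select_panel()].
#' @param round assessment round tag in the rating table.
#' @return list of class `assessment_result` with `leaf_scores`,
#'   `layer_scores` and `qi`.
#' @export
evaluate_framework <- function(system, ratings, panel, round = NULL) {
  tree <- system$tree
  ratings <- tibble::as_tibble(ratings)
  if (!is.null(round)) ratings <- ratings[ratings$round == round, , drop = FALSE]
  if (any(ratings$rating < 1 | ratings$rating > 10)) {
    stop("assessment ratings must lie in 1..10 (no deletion votes)",
         call. = FALSE)
  }
  leaves <- active_leaves(tree)
  missing_ids <- setdiff(leaves, unique(ratings$indicator_id))
  if (length(missing_ids) > 0) {
    stop("assessment ratings missing for indicator(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  wtab <- setNames(panel$included$weight, panel$included$expert_id)
  leaf_scores <- vapply(leaves, function(id) {
    rr <- ratings[ratings$indicator_id == id, , drop = FALSE]
    weighted_mean_rating(rr$rating, wtab[rr$expert_id])
  }, numeric(1))
  agg <- aggregate_scores(tree, leaf_scores)
  structure(list(leaf_scores = leaf_scores, layer_scores = agg$scores,
                 qi = agg$qi),
            class = "assessment_result")
}
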