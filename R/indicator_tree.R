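#' @importFrom stats pchisq rnorm runif sd var optim setNames
#' @importFrom utils read.csv write.csv head
NULL

# Statuses that count as part of the current indicator system. Indicators are
# never physically removed; screening/revision marks them "deleted" so that
# round-over-round diffs stay reproducible.
ACTIVE_STATUSES <- c("active", "added")

#' Round half-up
#'
#' Base R's `round()` rounds half to even; report values in this package follow
#' the half-up convention (8.915 -> 8.92), which is what printed composite
#' scores and weights use.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-12) / m
}

#' Construct a three-layer indicator tree
#'
#' An indicator tree is the forest of evaluation indicators: first-layer
#' dimensions, second-layer criteria and third-layer items. Each indicator has
#' a stable id (identity survives relabelling between Delphi rounds), a display
#' label, an optional long definition, its layer, a parent id (absent for
#' layer-1 dimensions), an optional normalised weight and a status
#' (`active`, `added` or `deleted`).
#'
#' @param indicators data frame with columns `id`, `label`, `layer` and
#'   optionally `definition`, `parent_id`, `weight`, `status`.
#' @param round_tag free-text tag recording which round the tree belongs to.
#' @return an object of class `indicator_tree`.
#' @export
indicator_tree <- function(indicators, round_tag = "") {
  ind <- tibble::as_tibble(indicators)
  if (!all(c("id", "label", "layer") %in% names(ind))) {
    stop("indicators need at least columns id, label, layer", call. = FALSE)
  }
  if (!"definition" %in% names(ind)) ind$definition <- ""
  if (!"parent_id" %in% names(ind)) ind$parent_id <- NA_character_
  if (!"weight" %in% names(ind)) ind$weight <- NA_real_
  if (!"status" %in% names(ind)) ind$status <- "active"
  ind$id <- as.character(ind$id)
  ind$parent_id <- as.character(ind$parent_id)
  ind$layer <- as.integer(ind$layer)
  ind$weight <- as.numeric(ind$weight)
  ind <- ind[, c("id", "label", "definition", "layer", "parent_id",
                 "weight", "status")]
  structure(list(indicators = ind, round_tag = round_tag),
            class = "indicator_tree")
}

#' @export
print.indicator_tree <- function(x, ...) {
  cnt <- count_indicators(x)
  cat(sprintf("<indicator_tree%s: %d active indicators (%s by layer)>\n",
              if (nzchar(x$round_tag)) paste0(" ", x$round_tag) else "",
              cnt$total, paste(cnt$by_layer, collapse = "/")))
  invisible(x)
}

is_active <- function(status) status %in% ACTIVE_STATUSES

active_indicators <- function(tree) {
  tree$indicators[is_active(tree$indicators$status), , drop = FALSE]
}

#' Validate an indicator tree
#'
#' Checks structural invariants: unique ids, parents exist, layer-k indicators
#' hang under layer-(k-1) parents (dimensions have no parent), weights in
#' [0, 1], and -- where sibling weights are set -- each sibling group's weights
#' summing to one.
#'
#' @param tree an `indicator_tree`.
#' @param weight_tol tolerance on sibling weight sums (default 1e-9).
#' @return a tibble of violations with columns `id` and `rule`; zero rows when
#'   the tree is well formed.
#' @export
validate_tree <- function(tree, weight_tol = 1e-9) {
  ind <- tree$indicators
  bad <- list()
  note <- function(id, rule) tibble::tibble(id = id, rule = rule)

  dup <- unique(ind$id[duplicated(ind$id)])
  for (id in dup) bad[[length(bad) + 1L]] <- note(id, "duplicate-id")

  for (i in seq_len(nrow(ind))) {
    row <- ind[i, ]
    if (!row$layer %in% 1:3) {
      bad[[length(bad) + 1L]] <- note(row$id, "layer-out-of-range")
      next
    }
    if (row$layer == 1L) {
      if (!is.na(row$parent_id)) {
        bad[[length(bad) + 1L]] <- note(row$id, "layer1-has-parent")
      }
    } else {
      if (is.na(row$parent_id)) {
        bad[[length(bad) + 1L]] <- note(row$id, "missing-parent")
      } else {
        p <- match(row$parent_id, ind$id)
        if (is.na(p)) {
          bad[[length(bad) + 1L]] <- note(row$id, "unknown-parent")
        } else if (ind$layer[p] != row$layer - 1L) {
          bad[[length(bad) + 1L]] <- note(row$id, "parent-wrong-layer")
        }
      }
    }
    if (!is.na(row$weight) && (row$weight < 0 || row$weight > 1)) {
      bad[[length(bad) + 1L]] <- note(row$id, "weight-out-of-range")
    }
    if (!row$status %in% c(ACTIVE_STATUSES, "deleted")) {
      bad[[length(bad) + 1L]] <- note(row$id, "unknown-status")
    }
  }

  # sibling groups with weights fully set must sum to 1
  act <- active_indicators(tree)
  grp <- split(act, ifelse(is.na(act$parent_id), "__root__", act$parent_id))
  for (g in grp) {
    if (all(!is.na(g$weight)) && nrow(g) > 0) {
      if (abs(sum(g$weight) - 1) > weight_tol) {
        bad[[length(bad) + 1L]] <- note(paste(g$id, collapse = ","),
                                        "sibling-weights-not-normalised")
      }
    }
  }

  if (length(bad) == 0) {
    tibble::tibble(id = character(), rule = character())
  } else {
    do.call(rbind, bad)
  }
}

#' Count active indicators per layer
#'
#' @param tree an `indicator_tree`.
#' @return list with `by_layer` (named integer vector for layers 1..3) and
#'   `total`.
#' @export
count_indicators <- function(tree) {
  act <- active_indicators(tree)
  by_layer <- vapply(1:3, function(l) sum(act$layer == l), integer(1))
  names(by_layer) <- paste0("layer", 1:3)
  list(by_layer = by_layer, total = sum(by_layer))
}

children_of <- function(ind, id) ind$id[!is.na(ind$parent_id) & ind$parent_id == id]

#' Apply deletions and additions to an indicator tree
#'
#' Deleting an indicator marks its whole subtree deleted; after deletions, any
#' second-layer indicator left with no active third-layer children is deleted
#' automatically, and likewise a first-layer dimension with no active children
#' (the cascade rule of the two-round protocol works in both directions).
#' Additions are appended with status `added` and must reference an active
#' parent.
#'
#' @param tree an `indicator_tree`.
#' @param deletions character vector of indicator ids to delete.
#' @param additions data frame of new indicators (columns as in
#'   [indicator_tree()]).
#' @return a new `indicator_tree`; the input is not modified.
#' @export
prune_and_extend <- function(tree, deletions = character(), additions = NULL) {
  ind <- tree$indicators
  missing_ids <- setdiff(deletions, ind$id)
  if (length(missing_ids) > 0) {
    stop("unknown indicator id(s) in deletions: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }

  # downward cascade: deleting a node deletes its subtree
  to_delete <- unique(as.character(deletions))
  frontier <- to_delete
  while (length(frontier) > 0) {
    kids <- unlist(lapply(frontier, children_of, ind = ind), use.names = FALSE)
    kids <- setdiff(kids, to_delete)
    to_delete <- c(to_delete, kids)
    frontier <- kids
  }
  ind$status[ind$id %in% to_delete] <- "deleted"

  # upward cascade: parents left without active children are deleted
  for (layer in c(2L, 1L)) {
    for (id in ind$id[ind$layer == layer & is_active(ind$status)]) {
      kids <- children_of(ind, id)
      if (length(kids) > 0 && !any(is_active(ind$status[ind$id %in% kids]))) {
        ind$status[ind$id == id] <- "deleted"
      }
    }
  }

  if (!is.null(additions) && nrow(additions) > 0) {
    add <- indicator_tree(additions)$indicators
    add$status <- "added"
    for (i in seq_len(nrow(add))) {
      if (add$layer[i] > 1L) {
        p <- match(add$parent_id[i], ind$id)
        if (is.na(p) || !is_active(ind$status[p])) {
          stop("addition '", add$id[i], "' references a missing or deleted ",
               "parent '", add$parent_id[i], "'", call. = FALSE)
        }
      }
      if (add$id[i] %in% ind$id) {
        stop("addition '", add$id[i], "' duplicates an existing id",
             call. = FALSE)
      }
    }
    ind <- rbind(ind, add)
  }

  indicator_tree(ind, round_tag = tree$round_tag)
}

#' Relabel indicators without changing identity
#'
#' Wording revisions between Delphi rounds change labels and definitions only;
#' ids, structure and statuses are untouched.
#'
#' @param tree an `indicator_tree`.
#' @param relabels data frame with columns `id` and any of `label`,
#'   `definition`.
#' @return a new `indicator_tree`.
#' @export
relabel_indicators <- function(tree, relabels) {
  ind <- tree$indicators
  for (i in seq_len(nrow(relabels))) {
    j <- match(as.character(relabels$id[i]), ind$id)
    if (is.na(j)) {
      stop("unknown indicator id in relabels: ", relabels$id[i], call. = FALSE)
    }
    if ("label" %in% names(relabels)) ind$label[j] <- relabels$label[i]
    if ("definition" %in% names(relabels)) {
      ind$definition[j] <- relabels$definition[i]
    }
  }
  indicator_tree(ind, round_tag = tree$round_tag)
}

#' Normalise indicator weights from weighted means
#'
#' Within every sibling group (indicators sharing a parent; the first-layer
#' dimensions form one group), an indicator's weight is its competency-weighted
#' mean importance divided by the group sum, so weight ratios equal
#' weighted-mean ratios and each group's weights sum to one.
#'
#' @param tree an `indicator_tree`.
#' @param weighted_means named numeric vector of weighted mean importance for
#'   every active indicator.
#' @return a new `indicator_tree` with `weight` set on active indicators.
#' @export
normalize_weights <- function(tree, weighted_means) {
  act <- active_indicators(tree)
  missing_ids <- setdiff(act$id, names(weighted_means))
  if (length(missing_ids) > 0) {
    stop("missing weighted mean for indicator(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  bad <- act$id[!is.finite(weighted_means[act$id]) | weighted_means[act$id] <= 0]
  if (length(bad) > 0) {
    stop("non-positive weighted mean for indicator(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ind <- tree$indicators
  groups <- split(act$id, ifelse(is.na(act$parent_id), "__root__", act$parent_id))
  for (ids in groups) {
    wm <- weighted_means[ids]
    ind$weight[match(ids, ind$id)] <- wm / sum(wm)
  }
  indicator_tree(ind, round_tag = tree$round_tag)
}

active_leaves <- function(tree) {
  act <- active_indicators(tree)
  has_active_child <- vapply(act$id, function(id) {
    any(act$parent_id %in% id)
  }, logical(1))
  act$id[!has_active_child]
}

#' Aggregate leaf scores up the indicator tree to a quality index
#'
#' Leaf indicators (active indicators with no active children; third-layer
#' items in a full tree) carry the final scores. Every upper-layer score is the
#' weight-weighted sum of its children's scores, and the quality index (QI) is
#' the weighted sum over the first-layer dimensions. Because weights are
#' normalised per sibling group, every aggregate is a convex combination and
#' stays on the 0-10 rating scale.
#'
#' @param tree an `indicator_tree` with normalised weights on active
#'   indicators.
#' @param leaf_scores named numeric vector of scores for every active leaf.
#' @return list with `scores` (named vector over all active indicators) and
#'   `qi` (the overall quality index).
#' @export
aggregate_scores <- function(tree, leaf_scores) {
  act <- active_indicators(tree)
  leaves <- active_leaves(tree)
  missing_ids <- setdiff(leaves, names(leaf_scores))
  if (length(missing_ids) > 0) {
    stop("missing score for leaf indicator(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(act$weight))) {
    stop("tree weights are not set; run normalize_weights() first",
         call. = FALSE)
  }
  scores <- setNames(rep(NA_real_, nrow(act)), act$id)
  scores[leaves] <- as.numeric(leaf_scores[leaves])
  for (layer in c(2L, 1L)) {
    for (id in act$id[act$layer == layer]) {
      if (!is.na(scores[id])) next  # already a leaf
      kids <- act$id[act$parent_id %in% id]
      scores[id] <- sum(scores[kids] * act$weight[match(kids, act$id)])
    }
  }
  top <- act$id[act$layer == min(act$layer)]
  qi <- sum(scores[top] * act$weight[match(top, act$id)])
  list(scores = scores, qi = qi)
}
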