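# In-code fixtures and independent oracles shared across the test files.

# A small but fully three-layer tree: 2 dimensions, 3 criteria, 6 items.
toy_tree <- function() {
  indicator_tree(data.frame(
    id        = c("A", "B", "A1", "A2", "B1",
                  "A1.1", "A1.2", "A2.1", "A2.2", "B1.1", "B1.2"),
    label     = c("Dim A", "Dim B", "Crit A1", "Crit A2", "Crit B1",
                  "a11", "a12", "a21", "a22", "b11", "b12"),
    layer     = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L, 3L),
    parent_id = c(NA, NA, "A", "A", "B",
                  "A1", "A1", "A2", "A2", "B1", "B1"),
    stringsAsFactors = FALSE
  ), round_tag = "toy")
}

# Equal-weight version of the toy tree (every sibling group uniform).
toy_tree_weighted <- function() {
  tr <- toy_tree()
  ids <- tr$indicators$id
  wm <- stats::setNames(rep(8, length(ids)), ids)
  normalize_weights(tr, wm)
}

toy_panel <- function(n = 4, weights = NULL) {
  if (is.null(weights)) weights = rep(60, n)
  list(included = tibble::tibble(
    expert_id = sprintf("E%02d", seq_len(n)),
    weight = weights
  ), excluded = character(), threshold = 50)
}

# Full-block rating table: every expert rates every active indicator `value`
# (or per-indicator values given as a named vector).
constant_ratings <- function(tree, panel, value = 8, round = 1L) {
  ids <- active_indicators_ids(tree)
  grid <- expand.grid(expert_id = panel$included$expert_id,
                      indicator_id = ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  v <- if (length(value) == 1) rep(value, nrow(grid)) else value[grid$indicator_id]
  tibble::tibble(expert_id = grid$expert_id, indicator_id = grid$indicator_id,
                 round = as.integer(round), rating = as.integer(v))
}

active_indicators_ids <- function(tree) {
  tree$indicators$id[tree$indicators$status %in% c("active", "added")]
}

# ---- independent oracles -------------------------------------------------

# Brute-force tie-corrected Kendall's W: explicit mid-ranks by counting, the
# sum-of-squared-rank-sums formula, per-judge tie terms from a frequency scan.
oracle_kendall_w <- function(mat) {
  b <- nrow(mat); k <- ncol(mat)
  ranks <- matrix(0, b, k)
  tie_sum <- 0
  for (i in seq_len(b)) {
    x <- mat[i, ]
    for (j in seq_len(k)) {
      # mid-rank: (# strictly smaller) + (1 + # equal) / 2
      ranks[i, j] <- sum(x < x[j]) + (1 + sum(x == x[j])) / 2
    }
    for (v in unique(x)) {
      t <- sum(x == v)
      tie_sum <- tie_sum + (t^3 - t)
    }
  }
  R <- colSums(ranks)
  num <- 12 * sum(R^2) - 3 * b^2 * k * (k + 1)^2
  den <- b^2 * k * (k^2 - 1) - b * tie_sum
  num / den
}

# Cronbach's alpha from a covariance matrix (closed form).
oracle_alpha_from_cov <- function(C) {
  p <- nrow(C)
  p / (p - 1) * (1 - sum(diag(C)) / sum(C))
}

# Item->factor map for a p-item, three-factor simple structure.
three_factor_map <- function(p = 9) {
  stopifnot(p %% 3 == 0)
  stats::setNames(rep(c("F1", "F2", "F3"), each = p / 3),
                  sprintf("it%02d", seq_len(p)))
}

# Data whose sample covariance equals Sigma exactly (Gram-matrix trick:
# scale the principal components of a centred Gaussian draw).
data_with_exact_cov <- function(n, Sigma, seed = 1) {
  p <- nrow(Sigma)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * p), n, p)
  })
  x <- scale(x, center = TRUE, scale = FALSE)
  C <- stats::cov(x)
  x <- x %*% solve(chol(C)) %*% chol(Sigma)
  colnames(x) <- rownames(Sigma)
  x
}
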