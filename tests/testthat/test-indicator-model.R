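test_that("validate_tree reports structural and normalization violations", {
  expect_equal(nrow(validate_tree(toy_tree())), 0)

  ind <- toy_tree()$indicators
  ind$parent_id[ind$id == "A1.1"] <- "A"  # layer-3 under a layer-1 node
  bad <- validate_tree(indicator_tree(ind))
  expect_equal(bad$rule, "parent-wrong-layer")
  expect_equal(bad$id, "A1.1")

  ind <- toy_tree()$indicators
  ind$weight[ind$id %in% c("A", "B")] <- c(0.6, 0.5)
  bad <- validate_tree(indicator_tree(ind))
  expect_true("sibling-weights-not-normalised" %in% bad$rule)
})

test_that("normalize_weights is proportional to weighted means within sibling groups", {
  tr <- indicator_tree(data.frame(
    id = c("S", "R", "C"), label = c("s", "r", "c"), layer = 1L,
    stringsAsFactors = FALSE))
  wm <- c(S = 9.69, R = 9.60, C = 9.13)
  out <- normalize_weights(tr, wm)
  w <- setNames(out$indicators$weight, out$indicators$id)
  # brute-force normalization oracle
  expect_equal(unname(w[c("S", "R", "C")]), unname(wm / sum(wm)),
               tolerance = 1e-12)
  expect_equal(round_half_up(unname(w[c("S", "R", "C")]), 3),
               c(0.341, 0.338, 0.321))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # equal means -> equal weights; singleton group -> 1
  tr2 <- toy_tree()
  wm2 <- setNames(rep(8, 11), tr2$indicators$id)
  out2 <- normalize_weights(tr2, wm2)
  w2 <- setNames(out2$indicators$weight, out2$indicators$id)
  expect_equal(unname(w2[c("A1", "A2")]), c(0.5, 0.5))
  expect_equal(unname(w2[["B1"]]), 1.0)  # single-child group

  expect_error(normalize_weights(tr, c(S = 9, R = 0, C = 9)), "non-positive")
  expect_error(normalize_weights(tr, c(S = 9, R = 9)), "missing")
})

test_that("weight conservation holds for every sibling group after normalization", {
  tr <- load_tree(system.file("extdata", "tree_round2_synthetic.json",
                              package = "delphiqi"))
  ids <- tr$indicators$id
  withr::with_seed(42, wm <- setNames(runif(length(ids), 7.5, 9.9), ids))
  out <- normalize_weights(tr, wm)
  act <- out$indicators
  grp <- split(act$weight, ifelse(is.na(act$parent_id), ".", act$parent_id))
  for (g in grp) expect_equal(sum(g), 1, tolerance = 1e-12)
})

test_that("aggregate_scores computes convex bottom-up aggregates and the QI", {
  tr <- toy_tree_weighted()
  leaves <- c(A1.1 = 10, A1.2 = 0, A2.1 = 8, A2.2 = 8, B1.1 = 8, B1.2 = 8)
  # reweight one pair to {0.3, 0.7} for a hand-computed parent score
  ind <- tr$indicators
  ind$weight[ind$id == "A1.1"] <- 0.3
  ind$weight[ind$id == "A1.2"] <- 0.7
  tr2 <- indicator_tree(ind, "toy")
  agg <- aggregate_scores(tr2, leaves)
  expect_equal(unname(agg$scores[["A1"]]), 3.0)  # 10*0.3 + 0*0.7

  # constant leaves -> every aggregate equals the constant, exactly
  agg_c <- aggregate_scores(tr, setNames(rep(7, 6), names(leaves)))
  expect_true(all(agg_c$scores == 7))
  expect_identical(agg_c$qi, 7)

  # scale equivariance and monotonicity
  base <- setNames(c(9, 8, 7, 6, 5, 4), names(leaves))
  q1 <- aggregate_scores(tr, base)$qi
  expect_equal(aggregate_scores(tr, base * 1.1)$qi, q1 * 1.1,
               tolerance = 1e-12)
  bumped <- base; bumped["B1.2"] <- bumped["B1.2"] + 1
  expect_gt(aggregate_scores(tr, bumped)$qi, q1)
  expect_true(q1 >= min(base) && q1 <= max(base))

  expect_error(aggregate_scores(tr, base[-1]), "missing score")
})

test_that("prune_and_extend cascades deletions both ways and appends additions", {
  tr <- toy_tree()
  # deleting all children of A1 deletes A1
  out <- prune_and_extend(tr, deletions = c("A1.1", "A1.2"))
  st <- setNames(out$indicators$status, out$indicators$id)
  expect_equal(unname(st[["A1"]]), "deleted")
  expect_equal(unname(st[["A"]]), "active")  # A still has A2's subtree

  # deleting a layer-2 node deletes its subtree; B then loses its only child
  out2 <- prune_and_extend(tr, deletions = "B1")
  st2 <- setNames(out2$indicators$status, out2$indicators$id)
  expect_equal(unname(st2[c("B1.1", "B1.2", "B")]), rep("deleted", 3))

  # additions appended with status "added" and counted as active
  add <- data.frame(id = "A1.3", label = "new", layer = 3L, parent_id = "A1",
                    stringsAsFactors = FALSE)
  out3 <- prune_and_extend(tr, additions = add)
  expect_equal(count_indicators(out3)$total, 12)
  expect_equal(out3$indicators$status[out3$indicators$id == "A1.3"], "added")

  expect_error(prune_and_extend(out2, additions = data.frame(
    id = "B1.3", label = "x", layer = 3L, parent_id = "B1",
    stringsAsFactors = FALSE)), "deleted")
  expect_error(prune_and_extend(tr, deletions = "nope"), "unknown")
})

test_that("disjoint deletions are order-independent", {
  tr <- toy_tree()
  a <- prune_and_extend(prune_and_extend(tr, "A1.1"), "B1.2")
  b <- prune_and_extend(prune_and_extend(tr, "B1.2"), "A1.1")
  expect_identical(a$indicators$status, b$indicators$status)
})

test_that("count_indicators reflects per-layer active counts", {
  r1 <- load_tree(system.file("extdata", "tree_round1_synthetic.json",
                              package = "delphiqi"))
  expect_equal(unname(count_indicators(r1)$by_layer), c(3L, 10L, 27L))
  expect_equal(count_indicators(r1)$total, 40L)

  empty <- indicator_tree(data.frame(id = character(), label = character(),
                                     layer = integer(),
                                     stringsAsFactors = FALSE))
  expect_equal(count_indicators(empty)$total, 0L)
})

test_that("relabelling changes wording but not identity or counts", {
  tr <- toy_tree()
  out <- relabel_indicators(tr, data.frame(id = "A1", label = "Criterion A1 v2",
                                           stringsAsFactors = FALSE))
  expect_equal(out$indicators$label[out$indicators$id == "A1"],
               "Criterion A1 v2")
  expect_identical(count_indicators(out), count_indicators(tr))
  expect_identical(out$indicators$id, tr$indicators$id)
})
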