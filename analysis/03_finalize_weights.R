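#!/usr/bin/env Rscript
# Stage 3: finalize the weighted evaluation system.
# Round-2 weighted means set the normalised weights within every sibling
# group; the weighted tree is the instrument used for the assessment survey.

suppressPackageStartupMessages(library(delphiqi))

panel <- select_panel(load_panel("results/sim/panel.csv"))
ratings <- load_ratings("results/sim/ratings.csv")
r2_tree <- load_tree("results/tree_round2.json")

round2 <- run_round(r2_tree, ratings[ratings$round == 2L, ], panel, round = 2L)
system <- finalize_system(r2_tree, round2)

act <- system$tree$indicators
dims <- act[act$layer == 1, ]
cat("First-layer dimension weights (round-2 weighted means, normalised):\n")
for (i in seq_len(nrow(dims))) {
  cat(sprintf("  %-20s %.3f\n", dims$label[i], round_half_up(dims$weight[i], 3)))
}
cat(sprintf("  sum of dimension weights: %.12f\n", sum(dims$weight)))

write.csv(act[, c("id", "label", "layer", "parent_id", "weight")],
          "results/final_weights.csv", row.names = FALSE)
save_tree(system$tree, "results/tree_weighted.json")
cat("Weighted evaluation system written to results/tree_weighted.json\n")
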