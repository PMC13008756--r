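#!/usr/bin/env Rscript
# Stage 4: score the framework.
# Third-layer final scores are the competency-weighted means of the
# assessment ratings (round 3 of the simulated survey); upper layers and the
# overall quality index follow by weighted aggregation.

suppressPackageStartupMessages(library(delphiqi))

panel <- select_panel(load_panel("results/sim/panel.csv"))
ratings <- load_ratings("results/sim/ratings.csv")
tree <- load_tree("results/tree_weighted.json")
system <- structure(list(tree = tree, provenance = 2L),
                    class = "evaluation_system")

ind <- tree$indicators
l3 <- ind$id[ind$layer == 3 & ind$status %in% c("active", "added")]
assess <- ratings[ratings$round == 3L & ratings$indicator_id %in% l3, ]
result <- evaluate_framework(system, assess, panel)

cat(sprintf("Quality index (QI): %.2f on the 0-10 scale\n",
            round_half_up(result$qi, 2)))
dims <- ind[ind$layer == 1, ]
for (i in seq_len(nrow(dims))) {
  cat(sprintf("  %-20s %.2f\n", dims$label[i],
              round_half_up(result$layer_scores[[dims$id[i]]], 2)))
}

scores <- data.frame(id = names(result$layer_scores),
                     score = unname(result$layer_scores))
write.csv(scores, "results/layer_scores.csv", row.names = FALSE)
report <- render_report(
  list(qi = result$qi,
       layer_scores = result$layer_scores[dims$id],
       weights = setNames(dims$weight, dims$id)),
  format = "json",
  provenance = list(seed = 2026, stage = "evaluation"))
writeLines(report, "results/evaluation_report.json")
cat("Report written to results/evaluation_report.json\n")
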