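#!/usr/bin/env Rscript
# Stage 2: run the two Delphi rounds.
# Round 1 on the 40-indicator tree, apply the three expert-comment additions,
# then Round 2 on the 43-indicator tree. Writes per-indicator statistics and
# the panel-level concordance for each round.

suppressPackageStartupMessages(library(delphiqi))
dir.create("results", showWarnings = FALSE)

panel <- select_panel(load_panel("results/sim/panel.csv"))
ratings <- load_ratings("results/sim/ratings.csv")

r1_tree <- load_tree(system.file("extdata", "tree_round1_synthetic.json",
                                 package = "delphiqi"))
round1 <- run_round(r1_tree, ratings[ratings$round == 1L, ], panel, round = 1L)
cat(sprintf("Round 1: %d indicators, %d excluded, W = %.3f (chi2 = %.1f, df = %d, p = %.3g)\n",
            nrow(round1$stats), length(round1$excluded),
            round1$consensus$w, round1$consensus$chi2,
            round1$consensus$df, round1$consensus$p))
write.csv(round1$stats, "results/round1_stats.csv", row.names = FALSE)

adds <- read.csv(system.file("extdata", "round1_additions_synthetic.csv",
                             package = "delphiqi"), stringsAsFactors = FALSE)
r2_tree <- apply_revisions(r1_tree, round1, additions = adds,
                           round_tag = "round2")
cnt <- count_indicators(r2_tree)
cat(sprintf("Revisions: +%d indicators -> %d active (%s by layer)\n",
            nrow(adds), cnt$total, paste(cnt$by_layer, collapse = "/")))

round2 <- run_round(r2_tree, ratings[ratings$round == 2L, ], panel, round = 2L)
cat(sprintf("Round 2: %d indicators, %d excluded, W = %.3f (chi2 = %.1f, df = %d, p = %.3g)\n",
            nrow(round2$stats), length(round2$excluded),
            round2$consensus$w, round2$consensus$chi2,
            round2$consensus$df, round2$consensus$p))
cat(sprintf("         weighted means %.2f..%.2f, CVs %.3f..%.3f\n",
            min(round2$stats$weighted_mean), max(round2$stats$weighted_mean),
            min(round2$stats$cv), max(round2$stats$cv)))
write.csv(round2$stats, "results/round2_stats.csv", row.names = FALSE)

consensus <- list(
  round1 = list(w = round1$consensus$w, chi2 = round1$consensus$chi2,
                df = round1$consensus$df, p = round1$consensus$p),
  round2 = list(w = round2$consensus$w, chi2 = round2$consensus$chi2,
                df = round2$consensus$df, p = round2$consensus$p)
)
jsonlite::write_json(consensus, "results/consensus.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
save_tree(r2_tree, "results/tree_round2.json")
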