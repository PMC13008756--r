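#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
# A 51-expert panel with competency scores in 51..89, per-round importance
# ratings for the packaged indicator trees, and factor-structured item
# responses for the 30 third-layer items. Everything is seeded; re-running
# reproduces the same files byte for byte.

suppressPackageStartupMessages(library(delphiqi))
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(seed = 2026, n_experts = 51)

panel_profiles <- generate_panel(cfg)
write.csv(panel_profiles, "results/sim/panel.csv", row.names = FALSE)
panel <- select_panel(panel_profiles)
cat(sprintf("Panel: %d experts generated, %d included (scores %.0f..%.0f)\n",
            nrow(panel_profiles), nrow(panel$included),
            min(panel$included$weight), max(panel$included$weight)))

r1_tree <- load_tree(system.file("extdata", "tree_round1_synthetic.json",
                                 package = "delphiqi"))
mu1 <- generate_importances(r1_tree, cfg)
ratings1 <- generate_delphi_ratings(r1_tree, panel, cfg, round = 1L,
                                    importances = mu1)

r2_tree <- load_tree(system.file("extdata", "tree_round2_synthetic.json",
                                 package = "delphiqi"))
mu2 <- generate_importances(r2_tree, cfg)
ratings2 <- generate_delphi_ratings(r2_tree, panel, cfg, round = 2L,
                                    importances = mu2)
# assessment survey: fresh ratings of the final system, stamped round 3
ratings3 <- generate_delphi_ratings(r2_tree, panel, cfg, round = 3L,
                                    importances = mu2)
ratings <- rbind(ratings1, ratings2, ratings3)
write.csv(ratings, "results/sim/ratings.csv", row.names = FALSE)
cat(sprintf("Ratings: %d records over rounds 1-3 (%d + %d indicators)\n",
            nrow(ratings), count_indicators(r1_tree)$total,
            count_indicators(r2_tree)$total))

# item responses for scale validation: third-layer items load on their
# first-layer dimension
ind <- r2_tree$indicators
l3 <- ind[ind$layer == 3 & ind$status %in% c("active", "added"), ]
dim_of <- vapply(l3$parent_id,
                 function(p) ind$parent_id[ind$id == p], character(1))
map <- setNames(dim_of, l3$id)
gen <- generate_factor_responses(map, cfg, n = 500)
write.csv(as.data.frame(gen$x), "results/sim/item_responses.csv",
          row.names = FALSE)
write.csv(data.frame(item = names(map), factor = unname(map),
                     true_loading = unname(gen$loadings)),
          "results/sim/item_map.csv", row.names = FALSE)
cat(sprintf("Item responses: %d x %d, true loadings %.2f..%.2f\n",
            nrow(gen$x), ncol(gen$x), min(gen$loadings), max(gen$loadings)))

prov <- list(seed = cfg$seed, n_experts = cfg$n_experts,
             rater_sd = cfg$rater_sd, deletion_prob = cfg$deletion_prob,
             importance_range = cfg$importance_range,
             loading_range = cfg$loading_range)
jsonlite::write_json(prov, "results/sim/provenance.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
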