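#!/usr/bin/env Rscript
# Stage 1: materialize the input data.
#
# Two datasets are written under results/data/:
#   * the deterministic "paper-shaped" dataset, whose structure matches the
#     reference essential-oil study by construction (91 compounds, 79
#     drug-like, 44 with targets, 191 targets, 70 pathways, hub ingredients
#     with 106 and 96 targets, a dominant pathway of 50 proteins);
#   * a fully random dataset drawn from the default simulation
#     configuration, used to exercise the pipeline away from the reference
#     numbers.

suppressMessages(library(netpharm))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- paper_shaped_dataset()
write_compound_table(ds$compounds, file.path(out, "compounds.tsv"))
write_interaction_table(ds$interactions, file.path(out, "interactions.tsv"))
write_gmt(ds$pathways, file.path(out, "pathways.gmt"))
writeLines(ds$background, file.path(out, "background.txt"))

cat("paper-shaped dataset:\n")
cat("  compounds:   ", nrow(ds$compounds), "\n")
cat("  interactions:", nrow(ds$interactions), "over",
    length(unique(ds$interactions$target_id)), "targets\n")
cat("  pathways:    ", length(ds$pathways), "(dominant",
    attr(ds$pathways, "dominant"), "with",
    length(ds$pathways$sets[[attr(ds$pathways, "dominant")]]), "proteins)\n")

cfg <- simulation_config(seed = 20260901)
sim_comp <- generate_compound_table(cfg)
sim_int <- generate_interactions(sim_comp, cfg)
sim_pw <- generate_pathway_sets(unique(sim_int$target_id), cfg)
sim_dir <- file.path(out, "simulated")
dir.create(sim_dir, showWarnings = FALSE)
write_compound_table(sim_comp, file.path(sim_dir, "compounds.tsv"))
write_interaction_table(sim_int, file.path(sim_dir, "interactions.tsv"))
write_gmt(sim_pw, file.path(sim_dir, "pathways.gmt"))

cat("random simulated dataset:", nrow(sim_comp), "compounds,",
    nrow(sim_int), "interactions,", length(sim_pw), "pathways\n")
cat("written to", out, "\n")
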