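#!/usr/bin/env Rscript
# Stage 4: construct the three graphs.
#
#   * the ingredient-target-pathway tripartite network,
#   * the core subnetwork around the highest-degree ("key") pathway,
#   * the pathway-based protein association projection (proteins joined
#     when they share at least one pathway, isolated proteins excluded).
#
# Graphs are exported in Pajek .net format with role partitions (.clu:
# 1 = ingredient, 2 = target, 3 = pathway).

suppressMessages(library(netpharm))

out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

interactions <- read_interaction_table("results/screening/interactions_kept.tsv")
pathways <- read_gmt("results/data/pathways.gmt")

tri <- build_tripartite(interactions, pathways)
core <- extract_core_subnetwork(tri)
proj <- project_protein_association(pathways, unique(interactions$target_id))

write_pajek(tri, file.path(out, "tripartite.net"), file.path(out, "tripartite.clu"))
write_pajek(core, file.path(out, "core.net"), file.path(out, "core.clu"))
write_pajek(proj, file.path(out, "projection.net"))

roles <- node_roles(tri)
core_roles <- node_roles(core)
key <- names(core_roles)[core_roles == "pathway"]
cat("tripartite:", igraph::vcount(tri), "nodes (",
    sum(roles == "ingredient"), "ingredients,", sum(roles == "target"),
    "targets,", sum(roles == "pathway"), "pathways ),",
    igraph::ecount(tri), "edges\n")
cat("core subnetwork around", key, "(",
    pathways$descriptions[[key]], "):", igraph::vcount(core), "nodes,",
    igraph::ecount(core), "edges\n")
cat("protein association projection:", igraph::vcount(proj), "nodes,",
    igraph::ecount(proj), "edges\n")
cat("written to", out, "\n")
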