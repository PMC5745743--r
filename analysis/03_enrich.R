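#!/usr/bin/env Rscript
# Stage 3: pathway over-representation on the screened target set.
#
# One-sided hypergeometric upper tail per pathway against the annotation
# universe, significance called on the raw p-value at 0.01 (the
# Benjamini-Hochberg adjusted p is reported alongside).

suppressMessages(library(netpharm))

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

interactions <- read_interaction_table("results/screening/interactions_kept.tsv")
pathways <- read_gmt("results/data/pathways.gmt")
background <- readLines("results/data/background.txt")

targets <- unique(interactions$target_id)
res <- enrich_pathways(targets, pathways, background = background,
                       alpha = 0.01, correction = "none")

utils::write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("tested", nrow(res), "pathways over a background of",
    length(background), "proteins\n")
cat("significant at raw p < 0.01:", sum(res$significant),
    " (BH-adjusted:", sum(res$p_adjusted < 0.01), ")\n")
top <- utils::head(res, 5)
cat("strongest enrichment:\n")
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-6s %-42s k=%3d/%-3d p=%.3g\n", top$pathway_id[i],
              top$description[i], top$overlap[i], top$pathway_size[i],
              top$p_value[i]))
}
cat("written to", out, "\n")
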