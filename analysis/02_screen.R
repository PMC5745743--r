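#!/usr/bin/env Rscript
# Stage 2: pre-network screening.
#
# Applies the drug-likeness filter (Lipinski rule of five: MW < 500,
# HBD <= 5, HBA <= 10, MlogP <= 5) and removes compounds without targets.
# The interaction table of the paper-shaped dataset is already
# support-filtered at its source database, so the target-support filter
# runs at min_support = 1 here; set it to 5 for raw interaction harvests.

suppressMessages(library(netpharm))

data_dir <- "results/data"
out <- "results/screening"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

compounds <- read_compound_table(file.path(data_dir, "compounds.tsv"))
interactions <- read_interaction_table(file.path(data_dir, "interactions.tsv"))

scr <- screen_dataset(compounds, interactions, min_support = 1)

write_compound_table(scr$compounds, file.path(out, "compounds_kept.tsv"))
write_interaction_table(scr$interactions, file.path(out, "interactions_kept.tsv"))
utils::write.table(scr$lipinski$flags, file.path(out, "lipinski_flags.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(scr$funnel, file.path(out, "funnel.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("screening funnel (compounds):",
    paste(scr$funnel$compounds, collapse = " -> "), "\n")
cat("rejected by Lipinski:", nrow(scr$lipinski$rejected), "compounds;",
    "violations:", paste(sort(unique(
      scr$lipinski$flags$violated[!scr$lipinski$flags$pass])), collapse = " "),
    "\n")
cat("targets retained:", length(unique(scr$interactions$target_id)), "\n")
cat("written to", out, "\n")
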