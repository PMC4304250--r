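#!/usr/bin/env Rscript
# Stage 5: SAM one-vs-rest differential expression per subtype; markers are
# the top 20 up-regulated genes at estimated FDR 0, ordered by fold change.

library(nmfsubtypes)

expr <- read_expression("results/cohort/expression_log2.tsv")
labels <- read.delim("results/clustering/labels.tsv")$subtype
truth <- readRDS("results/cohort/truth.rds")
dir.create("results/markers", showWarnings = FALSE, recursive = TRUE)

# discovered label ids are size-ordered; map each to its majority planted id
to_planted <- apply(table(labels, truth$labels), 1, which.max)

for (g in sort(unique(labels))) {
  tab <- sam_de(expr, labels, g, n_perm = 1000, seed = 20260924L + g)
  sel <- select_markers(tab, top_n = 20)
  write.table(sel, sprintf("results/markers/subtype%d_top20.tsv", g),
              sep = "\t", quote = FALSE, row.names = FALSE)
  planted <- truth$marker_ids[[to_planted[as.character(g)]]]
  cat(sprintf("subtype %d: %d markers selected, %.0f%% planted, fold change %.1f-%.1f\n",
              g, nrow(sel), 100 * mean(sel$gene_id %in% planted),
              min(sel$fold_change), max(sel$fold_change)))
}
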