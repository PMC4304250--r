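#!/usr/bin/env Rscript
# Stage 6: gene set enrichment between the two largest subtypes (the
# smallest is excluded: too few samples for a stable phenotype
# permutation). Sets at FDR q < 0.25 are reported per direction.

library(nmfsubtypes)

expr <- read_expression("results/cohort/expression_log2.tsv")
labels <- read.delim("results/clustering/labels.tsv")$subtype
gs <- read_gmt("results/cohort/genesets.gmt")
dir.create("results/gsea", showWarnings = FALSE, recursive = TRUE)

two <- as.integer(names(sort(table(labels), decreasing = TRUE))[1:2])
keep <- labels %in% two
et <- gsea_significance(expr[, keep], labels[keep], gs, n_perm = 1000,
                        seed = 20260924L)
write.table(et, "results/gsea/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("comparing subtypes %d vs %d (%d samples)\n", two[1], two[2],
            sum(keep)))
sig <- et[et$fdr_q < 0.25, ]
cat(sprintf("%d of %d sets at FDR q < 0.25:\n", nrow(sig), nrow(et)))
print(sig, digits = 3)
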