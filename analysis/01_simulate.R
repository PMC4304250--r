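#!/usr/bin/env Rscript
# Stage 1: generate the synthetic discovery cohort.
#
# The generator emulates the structure the downstream analyses assume: 96
# samples in three latent subtypes (43/45/8), subtype-specific marker genes
# shifted up on the log2 scale, exponential survival at per-subtype medians
# 37.6/19.2/13.8 months with the configured censoring fractions, and binary
# clinicopathologic covariates at per-subtype rates. Outputs go to
# results/cohort/ as plain text, plus a GMT with planted and decoy sets.

library(nmfsubtypes)

outdir <- "results/cohort"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(seed = 20260924L)
cohort <- simulate_cohort(cfg)

write_expression(cohort$expression, file.path(outdir, "expression_log2.tsv"))
write_clinical(cohort$clinical, file.path(outdir, "clinical.csv"))
write_gmt(simulate_genesets(cohort$truth, n_decoy_sets = 15, set_size = 50,
                            gene_ids = rownames(cohort$expression),
                            seed = cfg$seed),
          file.path(outdir, "genesets.gmt"))
saveRDS(cohort$truth, file.path(outdir, "truth.rds"))

cat(sprintf("cohort: %d genes x %d samples; subtype sizes %s\n",
            nrow(cohort$expression), ncol(cohort$expression),
            paste(table(cohort$truth$labels), collapse = "/")))
cat(sprintf("events observed: %d of %d\n", sum(cohort$clinical$event),
            nrow(cohort$clinical)))
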