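#!/usr/bin/env Rscript
# Stage 4: clinicopathologic association battery — contingency tables with
# within-subtype percentages, Fisher/chi-square tests for the binary
# covariates and Kruskal-Wallis for continuous ones (here: survival time
# as an illustration of the continuous path).

library(nmfsubtypes)

clinical <- read_clinical("results/cohort/clinical.csv")
labels <- read.delim("results/clustering/labels.tsv")$subtype
dir.create("results/associations", showWarnings = FALSE, recursive = TRUE)

rows <- list()
for (cv in c("r_status", "distant_met", "recurrence")) {
  ct <- crosstab(clinical, cv, labels)
  print(ct)
  p <- categorical_test(ct)
  cat(sprintf("  %s: p = %.3f\n", cv, p))
  rows[[cv]] <- data.frame(covariate = cv, p_value = round(p, 3))
}
kw <- kruskal_wallis(clinical$time_months, labels)
rows$time <- data.frame(covariate = "time_months (KW)",
                        p_value = round(kw$p_value, 3))

write.table(do.call(rbind, rows), "results/associations/tests.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
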