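#!/usr/bin/env Rscript
# Stage 3: Kaplan-Meier curves, median survival and log-rank comparisons
# between the discovered subtypes.

library(nmfsubtypes)

clinical <- read_clinical("results/cohort/clinical.csv")
labels <- read.delim("results/clustering/labels.tsv")
stopifnot(identical(clinical$sample_id, labels$sample_id))
dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)

rec <- data.frame(time = clinical$time_months, event = clinical$event,
                  group = labels$subtype)
groups <- sort(unique(rec$group))

medians <- vapply(groups, function(g) {
  median_survival(km_estimate(rec[rec$group == g, ]))
}, numeric(1))
pairs <- combn(groups, 2)
pairwise <- data.frame(
  group_a = pairs[1, ], group_b = pairs[2, ],
  p_value = apply(pairs, 2, function(p) logrank_test(rec, p[1], p[2])$p_value))
overall <- multigroup_logrank(rec)

write.table(data.frame(subtype = groups, median_months = medians,
                       n = as.vector(table(rec$group))),
            "results/survival/km_medians.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(pairwise, "results/survival/logrank_pairwise.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("median survival (months) by subtype:",
    paste(sprintf("%s=%.1f", groups, medians), collapse = ", "), "\n")
cat(sprintf("overall log-rank: chi2=%.2f (df=%d), p=%.4g\n",
            overall$statistic, overall$df, overall$p_value))
print(pairwise)
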