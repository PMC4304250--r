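test_that("signal-to-noise ranking matches the hand example and symmetry", {
  X <- rbind(g1 = c(2, 2, 2, 1, 1, 1))
  lab <- rep(c("A", "B"), each = 3)
  r <- rank_genes(X, lab)
  expect_equal(r$score, 2.5)  # 1 / (0.2 + 0.2) with both sds floored

  set.seed(1)
  X2 <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("g", 1:10), NULL))
  r_ab <- rank_genes(X2, factor(lab, levels = c("A", "B")))
  r_ba <- rank_genes(X2, factor(lab, levels = c("B", "A")))
  sc_ab <- setNames(r_ab$score, r_ab$gene_id)
  sc_ba <- setNames(r_ba$score, r_ba$gene_id)
  expect_equal(sc_ab[rownames(X2)], -sc_ba[rownames(X2)], tolerance = 1e-12)

  # a cleanly separated gene outranks null genes
  X3 <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("g", 1:10), NULL))
  X3["g7", ] <- c(9, 9, 9, 1, 1, 1)
  expect_equal(rank_genes(X3, lab)$gene_id[1], "g7")

  expect_error(rank_genes(X2, c("A", "A", "A", "A", "B", "B")), "3 samples")
  expect_error(rank_genes(X2, rep("A", 6)), "two phenotype classes")
})

test_that("enrichment score behaves as a weighted running sum", {
  ranked <- data.frame(gene_id = paste0("g", 1:100),
                       score = seq(5, 0.05, length.out = 100))
  top5 <- enrichment_score(ranked, paste0("g", 1:5))
  expect_gt(top5$ES, 0.9)
  expect_lte(abs(top5$ES), 1)

  # a set containing every gene carries no information
  allset <- enrichment_score(ranked, ranked$gene_id)
  expect_equal(allset$ES, 0)
  expect_equal(tail(allset$running_sum, 1), 0)

  # reversing the list flips the extremum sign for a one-sided set
  rev_ranked <- ranked[100:1, ]
  rev_ranked$score <- -rev(ranked$score)
  expect_lt(enrichment_score(rev_ranked, paste0("g", 1:5))$ES, 0)

  expect_error(enrichment_score(ranked, "absent"), "intersect")

  set.seed(3)
  for (i in 1:20) {
    es <- enrichment_score(ranked, sample(ranked$gene_id, 10))$ES
    expect_gte(es, -1); expect_lte(es, 1)
  }
})

test_that("planted gene sets reach the reporting FDR threshold", {
  co <- simulate_cohort(cohort_config(n_genes = 400, markers_per_subtype = 20,
                                      marker_log2_shift = 3, noise_sd = 0.5,
                                      seed = 17))
  gs <- simulate_genesets(co$truth, n_decoy_sets = 10, set_size = 20,
                          gene_ids = rownames(co$expression), seed = 2)
  keep <- co$truth$labels %in% c(1, 2)
  et <- gsea_significance(co$expression[, keep], co$truth$labels[keep], gs,
                          n_perm = 200, seed = 5)
  expect_s3_class(et, "enrichment_table")
  expect_true(all(abs(et$ES) <= 1))
  expect_true(all(diff(abs(et$NES)) <= 1e-12))
  q1 <- et$fdr_q[et$set_name == "SUBTYPE1_MARKERS"]
  q2 <- et$fdr_q[et$set_name == "SUBTYPE2_MARKERS"]
  expect_lt(q1, 0.25)
  expect_lt(q2, 0.25)
  expect_equal(et$direction[et$set_name == "SUBTYPE1_MARKERS"], "1")
  expect_equal(et$direction[et$set_name == "SUBTYPE2_MARKERS"], "2")
})

test_that("decoy sets on pure noise are rarely called enriched", {
  set.seed(9)
  X <- matrix(rnorm(300 * 24, 8, 1), 300, 24,
              dimnames = list(sprintf("G%03d", 1:300), NULL))
  gs <- lapply(1:15, function(i) sample(rownames(X), 20))
  names(gs) <- sprintf("DECOY_%02d", 1:15)
  et <- gsea_significance(X, rep(c("A", "B"), each = 12), gs,
                          n_perm = 150, seed = 4)
  expect_lte(mean(et$fdr_q < 0.25), 0.2)
})

test_that("GSEA is reproducible for a fixed seed and defaults to 1000 perms", {
  expect_identical(eval(formals(gsea_significance)$n_perm), 1000L)
  set.seed(2)
  X <- matrix(rnorm(150 * 12, 8, 1), 150, 12,
              dimnames = list(sprintf("G%03d", 1:150), NULL))
  gs <- list(S1 = sample(rownames(X), 25), S2 = sample(rownames(X), 25))
  lab <- rep(c("A", "B"), each = 6)
  e1 <- gsea_significance(X, lab, gs, n_perm = 120, seed = 7)
  e2 <- gsea_significance(X, lab, gs, n_perm = 120, seed = 7)
  expect_identical(e1, e2)

  expect_message(
    empty <- gsea_significance(X, lab, list(S = c("nope1", "nope2")),
                               n_perm = 120, seed = 1),
    "no gene set")
  expect_equal(nrow(empty), 0)
})
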