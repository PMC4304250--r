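test_that("noiseless construction puts marker rows at exactly two values", {
  co <- simulate_cohort(cohort_config(n_genes = 100, markers_per_subtype = 5,
                                      marker_log2_shift = 2, noise_sd = 0,
                                      seed = 1))
  for (s in 1:3) {
    rows <- co$expression[co$truth$marker_ids[[s]], , drop = FALSE]
    vals <- sort(unique(as.vector(rows)))
    expect_equal(vals, c(8, 10))
    in_sub <- co$truth$labels == s
    expect_true(all(rows[, in_sub] == 10))
    expect_true(all(rows[, !in_sub] == 8))
  }
})

test_that("default cohort has subtype sizes 43/45/8 and matching clinical table", {
  co <- simulate_cohort(cohort_config(n_genes = 50, markers_per_subtype = 5,
                                      seed = 42))
  expect_equal(unname(table(co$truth$labels)), array(c(43L, 45L, 8L)),
               ignore_attr = TRUE)
  expect_equal(nrow(co$clinical), 96L)
  expect_equal(co$clinical$subtype_true, unname(co$truth$labels))
  expect_equal(co$clinical$sample_id, colnames(co$expression))
})

test_that("survival times hit the configured medians without censoring", {
  cfg <- cohort_config(n_genes = 5, markers_per_subtype = 1,
                       subtype_sizes = c(10000L, 10000L, 10000L),
                       censor_rate_per_subtype = c(0, 0, 0), seed = 5)
  cl <- simulate_cohort(cfg)$clinical
  med <- unname(tapply(cl$time_months, cl$subtype_true, median))
  expect_true(all(abs(med - c(37.6, 19.2, 13.8)) / c(37.6, 19.2, 13.8) < 0.05))
  expect_true(all(cl$event == 1))
})

test_that("same seed and config reproduce identical output", {
  cfg <- cohort_config(n_genes = 80, markers_per_subtype = 5, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
})

test_that("marker effect approaches the configured shift as noise vanishes", {
  for (noise in c(0.3, 0.01)) {
    co <- small_cohort(seed = 3, noise = noise)
    diffs <- vapply(1:3, function(s) {
      rows <- co$expression[co$truth$marker_ids[[s]], , drop = FALSE]
      in_sub <- co$truth$labels == s
      mean(rows[, in_sub]) - mean(rows[, !in_sub])
    }, numeric(1))
    expect_equal(diffs, rep(2.5, 3), tolerance = max(5 * noise, 0.02))
  }
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_genes = 0), "positive")
  expect_error(cohort_config(survival_medians = c(10, -1, 5)), "positive")
  expect_error(cohort_config(subtype_sizes = c(4, 0, 3)), ">= 1")
  expect_error(cohort_config(n_genes = 10, markers_per_subtype = 5),
               "exceed")
  expect_error(cohort_config(censor_rate_per_subtype = c(0.5, 1.2, 0)),
               "censor")
})

test_that("gene-set simulation plants marker sets and round-trips as GMT", {
  co <- small_cohort(seed = 2)
  ids <- rownames(co$expression)
  bare <- simulate_genesets(co$truth, n_decoy_sets = 0, set_size = 10,
                            gene_ids = ids)
  expect_length(bare, 3)
  gs <- simulate_genesets(co$truth, n_decoy_sets = 5, set_size = 10,
                          gene_ids = ids, seed = 4)
  expect_length(gs, 8)
  expect_true(all(gs$SUBTYPE2_MARKERS %in% co$truth$marker_ids$subtype2))
  expect_error(simulate_genesets(co$truth, 2, set_size = 10000,
                                 gene_ids = ids), "universe")

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  expect_identical(read_gmt(path), gs)
})

test_that("expression and clinical tables survive a write/read round trip", {
  co <- simulate_cohort(cohort_config(n_genes = 30, markers_per_subtype = 2,
                                      seed = 6))
  ep <- withr::local_tempfile(fileext = ".tsv")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_expression(co$expression, ep)
  write_clinical(co$clinical, cp)
  expect_equal(read_expression(ep), co$expression, tolerance = 1e-12)
  expect_equal(read_clinical(cp), co$clinical, tolerance = 1e-12)
})
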