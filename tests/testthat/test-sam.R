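test_that("SAM d statistic matches hand evaluation and sign contract", {
  X <- rbind(flat = c(3, 3, 3, 3), up = c(4, 4, 2, 2))
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  d <- sam_statistic(X, mask, s0 = 0.5)
  expect_equal(unname(d["flat"]), 0)
  expect_equal(unname(d["up"]), 4)  # numerator 2, s = 0, s0 = 0.5

  set.seed(1)
  X2 <- matrix(rnorm(200), 20, 10)
  X2[1, 1:5] <- X2[1, 1:5] + 10
  d2 <- sam_statistic(X2, rep(c(TRUE, FALSE), each = 5))
  expect_gt(d2[1], 0)

  expect_error(sam_statistic(X2, rep(c(TRUE, FALSE), c(1, 9))),
               "at least 2")
})

test_that("d is invariant under adding a constant to a gene", {
  set.seed(2)
  X <- matrix(rnorm(120, 6), 12, 10)
  mask <- rep(c(TRUE, FALSE), each = 5)
  d1 <- sam_statistic(X, mask, s0 = 0.3)
  X[3, ] <- X[3, ] + 50
  d2 <- sam_statistic(X, mask, s0 = 0.3)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-9)
})

test_that("q-values are zero for strong planted markers and monotone in |d|", {
  co <- simulate_cohort(cohort_config(n_genes = 300, markers_per_subtype = 15,
                                      marker_log2_shift = 3, noise_sd = 0.5,
                                      seed = 14))
  mask <- co$truth$labels == 2
  q <- sam_qvalues(co$expression, mask, n_perm = 200, seed = 3)
  d <- sam_statistic(co$expression, mask)
  planted <- co$truth$marker_ids$subtype2
  expect_true(all(q[planted] == 0))

  ord <- order(-abs(d))
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
})

test_that("pure-noise matrices rarely reach small q", {
  set.seed(6)
  fracs <- vapply(1:3, function(i) {
    X <- matrix(rnorm(200 * 20, 8, 1), 200, 20)
    q <- sam_qvalues(X, rep(c(TRUE, FALSE), each = 10), n_perm = 150,
                     seed = 50 + i)
    mean(q < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.1)
})

test_that("few distinguishable permutations trigger full enumeration", {
  set.seed(4)
  X <- matrix(rnorm(40, 5), 8, 5)
  expect_message(q <- sam_qvalues(X, c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                  n_perm = 100, seed = 1),
                 "full enumeration")
  expect_true(all(q >= 0 & q <= 1))
})

test_that("marker selection applies the q=0 / fold-change / top-n rule", {
  tab <- data.frame(
    gene_id = paste0("g", 1:8),
    d_stat = c(5, 4, 3, 2, 1, -4, 0.5, 2.5),
    fold_change = c(4, 8, 2, 1.5, 3, 0.2, 1.2, 6),
    q_value = c(0, 0, 0, 0, 0.1, 0, 0.2, 0),
    subtype = 1
  )
  sel <- select_markers(tab, top_n = 3)
  expect_equal(sel$gene_id, c("g2", "g8", "g1"))
  expect_true(all(diff(sel$fold_change) <= 0))

  expect_message(all5 <- select_markers(tab, top_n = 20), "qualify")
  expect_equal(nrow(all5), 5)  # q = 0 and fold change > 1 only
  expect_true(all(all5$q_value == 0 & all5$fold_change > 1))
})

test_that("one-vs-rest marker tables recover the planted subtype block", {
  co <- simulate_cohort(cohort_config(n_genes = 300, markers_per_subtype = 15,
                                      marker_log2_shift = 3, noise_sd = 0.5,
                                      seed = 14))
  tab <- sam_de(co$expression, co$truth$labels, 3, n_perm = 200, seed = 5)
  sel <- select_markers(tab, top_n = 15)
  planted <- co$truth$marker_ids$subtype3
  expect_gte(mean(sel$gene_id %in% planted), 0.9)     # precision
  expect_gte(mean(planted %in% sel$gene_id), 0.9)     # recall
  expect_true(all(diff(sel$fold_change) <= 0))
})
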