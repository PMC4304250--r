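test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  k1 <- km_estimate(data.frame(time = c(1, 2, 3), event = 1))
  expect_equal(k1$surv, c(2 / 3, 1 / 3, 0))

  k2 <- km_estimate(data.frame(time = c(1, 2, 3), event = c(0, 1, 1)))
  expect_equal(k2$surv[k2$time == 2], 0.5)
  expect_equal(k2$surv[k2$time == 3], 0)

  all_cens <- km_estimate(data.frame(time = c(2, 5, 9), event = 0))
  expect_true(all(all_cens$surv == 1))

  expect_error(km_estimate(data.frame(time = numeric(0), event = numeric(0))),
               "non-empty")
  expect_error(km_estimate(data.frame(time = c(1, -2), event = c(1, 1))),
               "positive")
})

test_that("KM equals empirical survival when censoring is absent", {
  set.seed(11)
  for (i in 1:5) {
    times <- round(rexp(40, 1 / 20), 1) + 0.1
    k <- km_estimate(data.frame(time = times, event = 1))
    emp <- vapply(k$time, function(t) mean(times > t), numeric(1))
    expect_equal(k$surv, emp)
  }
})

test_that("median survival uses the first time S(t) <= 0.5", {
  k <- km_estimate(data.frame(time = c(5, 10), event = 1))
  expect_equal(median_survival(k), 5)  # S(5) = 0.5 exactly

  k4 <- km_estimate(data.frame(time = 1:4, event = 1))
  expect_equal(median_survival(k4), 2)

  nr <- km_estimate(data.frame(time = c(3, 6), event = 0))
  expect_true(is.na(median_survival(nr)))
})

test_that("log-rank statistic matches a hand O-E/V tabulation", {
  rec <- data.frame(time = c(1, 2, 10, 11), event = 1,
                    group = c("a", "a", "b", "b"))
  got <- logrank_test(rec, "a", "b")
  oracle <- logrank_by_hand(rec, "a", "b")
  expect_equal(got$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(got$p_value, oracle$p_value, tolerance = 1e-10)
  expect_gt(got$statistic, 0)
  expect_lt(got$p_value, 0.2)

  set.seed(4)
  rec2 <- data.frame(time = round(rexp(30, 1 / 15), 1) + 0.1,
                     event = rbinom(30, 1, 0.7),
                     group = rep(c("a", "b"), 15))
  got2 <- logrank_test(rec2, "a", "b")
  oracle2 <- logrank_by_hand(rec2, "a", "b")
  expect_equal(got2$statistic, oracle2$statistic, tolerance = 1e-8)
})

test_that("identical groups give zero statistic and swap leaves it unchanged", {
  rec <- data.frame(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1))
  both <- rbind(cbind(rec, group = "a"), cbind(rec, group = "b"))
  res <- logrank_test(both, "a", "b")
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  set.seed(9)
  rec2 <- data.frame(time = rexp(40, 1 / 10) + 0.1,
                     event = rbinom(40, 1, 0.8),
                     group = rep(c("x", "y"), 20))
  expect_equal(logrank_test(rec2, "x", "y")$statistic,
               logrank_test(rec2, "y", "x")$statistic, tolerance = 1e-12)
})

test_that("multigroup log-rank handles k groups and degenerate input", {
  rec <- data.frame(time = c(1, 2, 3), event = 1)
  three <- rbind(cbind(rec, group = "a"), cbind(rec, group = "b"),
                 cbind(rec, group = "c"))
  res <- multigroup_logrank(three)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$df, 2L)

  set.seed(3)
  rec2 <- data.frame(time = rexp(30, 1 / 12) + 0.1,
                     event = rbinom(30, 1, 0.7),
                     group = rep(c("a", "b"), 15))
  expect_equal(multigroup_logrank(rec2)$statistic,
               logrank_test(rec2, "a", "b")$statistic, tolerance = 1e-12)

  expect_error(multigroup_logrank(cbind(rec, group = "a")), "two groups")
  nocens <- data.frame(time = c(1, 2, 3, 4), event = 0,
                       group = c("a", "a", "b", "b"))
  expect_message(z <- multigroup_logrank(nocens), "no events")
  expect_equal(z$p_value, 1)
})

test_that("planted subtype survival differences are detected", {
  co <- simulate_cohort(cohort_config(n_genes = 5, markers_per_subtype = 1,
                                      survival_medians = c(60, 15, 5),
                                      censor_rate_per_subtype = c(0, 0, 0),
                                      seed = 31))
  rec <- surv_records(co$clinical)
  expect_lt(multigroup_logrank(rec)$p_value, 0.05)
})
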