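test_that("median dichotomization sends ties to the low group", {
  expect_equal(as.character(dichotomize_by_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(dichotomize_by_median(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  flat <- dichotomize_by_median(rep(2, 5))
  expect_true(all(flat == "low"))
  expect_true(attr(flat, "degenerate"))
  expect_error(dichotomize_by_median(1), ">= 2")

  withr::with_seed(111, {
    v <- sample(1:20, 50, replace = TRUE)
    grp <- dichotomize_by_median(v)
    n_ties <- sum(v == median(v))
    expect_lte(abs(sum(grp == "high") - sum(grp == "low")), n_ties)
  })
})

test_that("log-rank test agrees with the per-event-time hand computation", {
  # identical survival experience mirrored across the groups
  time <- c(5, 8, 12, 5, 8, 12)
  event <- c(1, 0, 1, 1, 0, 1)
  group <- rep(c("high", "low"), each = 3)
  same <- logrank_test(time, event, group)
  expect_lt(same$chi_square, 1e-10)
  expect_gt(same$p, 0.999)

  # toy 6-subject table with distinct event times
  time2 <- c(2, 4, 6, 3, 7, 9)
  event2 <- c(1, 1, 0, 1, 1, 1)
  group2 <- rep(c("high", "low"), each = 3)
  res <- logrank_test(time2, event2, group2)
  oracle <- logrank_by_hand(time2, event2, group2)
  expect_equal(res$chi_square, oracle$chi_square, tolerance = 1e-8)
  expect_equal(res$p, oracle$p, tolerance = 1e-8)

  # larger random table, including tied event times
  withr::with_seed(121, {
    n <- 60
    time3 <- sample(1:25, n, replace = TRUE)
    event3 <- rbinom(n, 1, 0.7)
    group3 <- rep(c("high", "low"), each = n / 2)
    res3 <- logrank_test(time3, event3, group3)
    oracle3 <- logrank_by_hand(time3, event3, group3)
    expect_equal(res3$chi_square, oracle3$chi_square, tolerance = 1e-8)
  })

  zero <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(zero$p, 1)
  expect_equal(zero$flag, "zero-events")
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two nonempty")
})

test_that("log-rank separates simulated hazard-ratio-3 groups", {
  withr::with_seed(131, {
    hits <- 0
    n_rep <- 20
    for (rep in seq_len(n_rep)) {
      n <- 200
      grp <- rep(c("high", "low"), each = n / 2)
      rate <- ifelse(grp == "high", 0.003 * 3, 0.003)
      t_ev <- rexp(n, rate)
      cens <- runif(n) < 0.3
      time <- ifelse(cens, runif(n) * t_ev, t_ev)
      if (logrank_test(time, as.integer(!cens), grp)$p < 0.01) hits <- hits + 1
    }
    expect_gte(hits / n_rep, 0.9)
  })
})

test_that("cohort product correlations compose z-scoring and products", {
  tumor <- random_expr(8, 40, seed = 141)
  dcls <- data.frame(gene_a = c("g001", "g003"), gene_b = c("g002", "g004"))

  full <- cohort_product_correlations(tumor, dcls)
  expect_equal(ncol(full), 40)

  excl <- colnames(tumor)[1:10]
  prods <- cohort_product_correlations(tumor, dcls, exclude_samples = excl)
  expect_equal(ncol(prods), 30)
  # composition oracle: manual z-score of the remaining cohort
  sub <- tumor[, -(1:10)]
  za <- as.numeric(scale(sub["g001", ]))
  zb <- as.numeric(scale(sub["g002", ]))
  expect_equal(unname(prods["g001|g002", ]), za * zb, tolerance = 1e-12)

  # a gene paired with itself gives squared z-scores summing to n - 1
  self <- cohort_product_correlations(tumor,
                                      data.frame(gene_a = "g001",
                                                 gene_b = "g001"))
  expect_true(all(self >= 0))
  expect_equal(sum(self) / (ncol(self) - 1), 1, tolerance = 1e-12)

  expect_error(cohort_product_correlations(tumor, dcls,
                                           exclude_samples = colnames(tumor)),
               "empty")
})

test_that("prognosis calling thresholds the survival FDR", {
  res <- data.frame(pair = c("a|b", "c|d"), p = c(1, 1), fdr = c(1, 1))
  expect_equal(nrow(call_prognosis_dcls(res, 0.3)), 0)
  expect_equal(nrow(call_prognosis_dcls(res, 1.0)), 2)
})

test_that("survival screen flags a planted prognosis pair among null links", {
  cfg <- planted_dc_config(seed = 151, n_subjects = 20, n_true = 10,
                           n_null = 40, rho_normal = 0, rho_tumor = 0.6,
                           n_extra_tumor = 200)
  cfg$prognosis_pairs <- data.frame(gene_a = "g0001", gene_b = "g0002",
                                    hazard_ratio = 3)
  co <- generate_cohort(cfg)
  paired_tumor <- co$metadata$sample_id[
    co$metadata$condition == "tumor" &
      co$metadata$subject_id %in% co$metadata$subject_id[
        co$metadata$condition == "normal"]]
  prods <- cohort_product_correlations(co$expr_tumor, co$pairs,
                                       exclude_samples = paired_tumor)
  subj <- setNames(co$metadata$subject_id, co$metadata$sample_id)
  scr <- survival_screen(prods, co$survival, subj)
  called <- call_prognosis_dcls(scr, 0.3)
  expect_true("g0001|g0002" %in% called$pair)
  expect_equal(called$worse_group[called$pair == "g0001|g0002"], "high")
})

test_that("Kaplan-Meier coordinates step down only at event times", {
  time <- c(2, 4, 6, 3, 7, 9)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("high", "low"), each = 3)
  km <- km_coordinates(time, event, group)
  expect_setequal(unique(km$group), c("high", "low"))
  for (g in c("high", "low")) {
    s <- km$surv[km$group == g]
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 1))
  }
})
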