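test_that("condition-wise correlations and labels behave on edge cases", {
  normal <- random_expr(6, 30, seed = 61)
  tumor <- random_expr(6, 25, seed = 62)

  self <- condition_pccs(data.frame(gene_a = "g001", gene_b = "g001"),
                         normal, tumor)
  expect_equal(self$pcc_normal, 1, tolerance = 1e-12)
  expect_equal(self$pcc_tumor, 1, tolerance = 1e-12)

  empty <- condition_pccs(data.frame(gene_a = character(0),
                                     gene_b = character(0)), normal, tumor)
  expect_equal(nrow(empty), 0)

  expect_error(condition_pccs(data.frame(gene_a = "gX", gene_b = "g001"),
                              normal, tumor), "gX")
})

test_that("planted condition correlations are recovered empirically", {
  withr::with_seed(71, {
    n <- 500
    xy_n <- sample_pair_expression(0.8, n)
    xy_t <- sample_pair_expression(0.2, n)
    normal <- t(xy_n); tumor <- t(xy_t)
    rownames(normal) <- rownames(tumor) <- c("gA", "gB")
    colnames(normal) <- paste0("n", 1:n)
    colnames(tumor) <- paste0("t", 1:n)
    tbl <- condition_pccs(data.frame(gene_a = "gA", gene_b = "gB"),
                          normal, tumor)
    expect_lt(abs(tbl$pcc_normal - 0.8), 0.1)
    expect_lt(abs(tbl$pcc_tumor - 0.2), 0.1)
    expect_equal(as.character(tbl$strength_change), "Weakened")
  })
})

test_that("strength fractions sum to one and ties count as Weakened", {
  tbl <- pair_correlation_table(c("a", "c"), c("b", "d"),
                                pcc_normal = c(0.8, -0.5),
                                pcc_tumor = c(0.3, 0.1))
  fr <- strength_fractions(tbl)
  expect_equal(unname(fr["strengthened"] + fr["weakened"]), 1)
  expect_equal(unname(fr["weakened"]), 1)

  tie <- pair_correlation_table("a", "b", pcc_normal = 0.4, pcc_tumor = -0.4)
  expect_equal(as.character(tie$strength_change), "Weakened")
  expect_error(strength_fractions(tbl[0, ]), "empty")
})

test_that("sign patterns follow the correlation signs", {
  tbl <- pair_correlation_table(
    c("a", "c", "e", "g"), c("b", "d", "f", "h"),
    pcc_normal = c(0.5, -0.5, -0.2, 0),
    pcc_tumor = c(0.3, 0.4, -0.6, 0.2))
  expect_equal(as.character(tbl$sign_pattern),
               c("same-signed positive", "differently signed",
                 "same-signed negative", "same-signed positive"))
})

test_that("cross-condition slope matches the closed-form OLS solution", {
  x <- seq(-0.9, 0.9, length.out = 25)
  ident <- pair_correlation_table(paste0("a", 1:25), paste0("b", 1:25), x, x)
  fit <- fit_cross_condition_slope(ident)
  expect_equal(unname(fit["slope"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit["intercept"]), 0, tolerance = 1e-12)

  half <- pair_correlation_table(paste0("a", 1:25), paste0("b", 1:25), x, 0.5 * x)
  expect_equal(unname(fit_cross_condition_slope(half)["slope"]), 0.5,
               tolerance = 1e-12)

  withr::with_seed(81, {
    y <- 0.5 * x + rnorm(25, sd = 0.05)
    y <- pmax(pmin(y, 1), -1)
    noisy <- pair_correlation_table(paste0("a", 1:25), paste0("b", 1:25), x, y)
    slope <- unname(fit_cross_condition_slope(noisy)["slope"])
    expect_equal(slope, cov(x, y) / var(x), tolerance = 1e-10)
  })

  degen <- pair_correlation_table(c("a", "c"), c("b", "d"), c(0.2, 0.2),
                                  c(0.1, 0.3))
  expect_error(fit_cross_condition_slope(degen), "degenerate")
})

test_that("half-thresholding equals brute-force enumeration and ranking", {
  normal <- random_expr(6, 40, seed = 91)
  tumor <- random_expr(6, 40, seed = 92)
  genes <- rownames(normal)

  all_sel <- half_threshold_pairs(genes, normal, tumor, top_fraction = 1)
  expect_equal(nrow(all_sel), choose(6, 2))  # 15 candidate pairs, all kept

  frac <- 0.3
  sel <- half_threshold_pairs(genes, normal, tumor, top_fraction = frac)

  # brute-force oracle over all 15 pairs
  combos <- combn(genes, 2)
  pn <- pt_ <- numeric(ncol(combos))
  for (i in seq_len(ncol(combos))) {
    pn[i] <- cor(normal[combos[1, i], ], normal[combos[2, i], ])
    pt_[i] <- cor(tumor[combos[1, i], ], tumor[combos[2, i], ])
  }
  k <- ceiling(frac * ncol(combos))
  top_n <- abs(pn) >= sort(abs(pn), decreasing = TRUE)[k]
  top_t <- abs(pt_) >= sort(abs(pt_), decreasing = TRUE)[k]
  oracle_keys <- paste(combos[1, top_n | top_t], combos[2, top_n | top_t],
                       sep = "|")
  sel_keys <- paste(sel$gene_a, sel$gene_b, sep = "|")
  expect_setequal(sel_keys, oracle_keys)

  # selection is a superset of each single-condition top set
  expect_true(all(paste(combos[1, top_n], combos[2, top_n], sep = "|")
                  %in% sel_keys))
  expect_true(all(paste(combos[1, top_t], combos[2, top_t], sep = "|")
                  %in% sel_keys))
})

test_that("asymmetric heatmap matrix combines the two conditions", {
  normal <- random_expr(5, 30, seed = 101)
  tumor <- random_expr(5, 30, seed = 102)
  genes <- rownames(normal)
  h <- asymmetric_heatmap_matrix(genes, normal, tumor)
  expect_equal(diag(h), setNames(rep(1, 5), genes))
  expect_equal(h[2, 1], cor(normal["g001", ], normal["g002", ]),
               tolerance = 1e-12)
  expect_equal(h[1, 2], cor(tumor["g001", ], tumor["g002", ]),
               tolerance = 1e-12)
  # cross-check lower triangle against condition_pccs
  tbl <- condition_pccs(data.frame(gene_a = "g001", gene_b = "g002"),
                        normal, tumor)
  expect_equal(h[2, 1], tbl$pcc_normal, tolerance = 1e-12)

  sym <- asymmetric_heatmap_matrix(genes, normal, normal)
  expect_equal(sym, t(sym), tolerance = 1e-12)
})
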