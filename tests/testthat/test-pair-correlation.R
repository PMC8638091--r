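test_that("z-scoring centers and scales rows, excluding constant genes", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  z <- zscore_genes(m)
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_equal(attr(z, "excluded"), "g2")
  expect_false("g2" %in% rownames(z))

  r <- random_expr(20, 15, seed = 3)
  zr <- zscore_genes(r)
  for (g in c("g001", "g013")) {
    expect_equal(mean(zr[g, ]), (mean(r[g, ]) - mean(r[g, ])), tolerance = 1e-12)
    expect_equal(sd(zr[g, ]), 1, tolerance = 1e-12)
  }
})

test_that("per-sample products recover the Pearson correlation identity", {
  z <- c(-1, 0, 1)
  expect_equal(product_correlation(z, z), c(1, 0, 1))
  expect_equal(sum(product_correlation(z, z)) / 2, 1)
  expect_equal(sum(product_correlation(z, -z)) / 2, -1)
  expect_error(product_correlation(z, c(1, 2)), "length")

  withr::with_seed(17, {
    for (n in c(5, 50, 500)) {
      for (rep in 1:20) {
        x <- rnorm(n)
        y <- 0.4 * x + rnorm(n)
        m <- rbind(a = x, b = y)
        colnames(m) <- paste0("s", seq_len(n))
        z2 <- zscore_genes(m)
        p <- product_correlation(z2["a", ], z2["b", ])
        expect_equal(sum(p) / (n - 1), cor(x, y), tolerance = 1e-10)
      }
    }
  })
})

test_that("paired CILP test matches the t-distribution oracle", {
  # identical products in both conditions
  v <- c(0.3, -1, 2, 0.5)
  same <- cilp_test_paired(v, v)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # zero-variance nonzero differences flagged degenerate, not dropped
  deg <- cilp_test_paired(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, .Machine$double.xmin)

  expect_error(cilp_test_paired(1:2, 3:4), ">= 3")

  withr::with_seed(5, {
    for (rep in 1:25) {
      n <- sample(4:40, 1)
      pn <- rnorm(n)
      pt_ <- rnorm(n, mean = 0.3)
      res <- cilp_test_paired(pn, pt_)
      d <- pt_ - pn
      t_oracle <- mean(d) / (sd(d) / sqrt(n))
      p_oracle <- 2 * pt(abs(t_oracle), df = n - 1, lower.tail = FALSE)
      expect_equal(res$p, p_oracle, tolerance = 1e-10)
      expect_equal(res$p, t.test(pt_, pn, paired = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  })
})

test_that("paired test equals intercept-only regression of differences", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- 30
      pn <- rnorm(n)
      pt_ <- pn + rnorm(n, 0.2, 0.5)
      p_paired <- cilp_test_paired(pn, pt_)$p
      fit <- summary(lm((pt_ - pn) ~ 1))
      expect_equal(p_paired, unname(fit$coefficients[1, 4]), tolerance = 1e-10)
    }
  })
})

test_that("regression CILP test matches a normal-equations oracle", {
  withr::with_seed(7, {
    n <- 80
    group <- rep(c(0, 1), each = n / 2)
    za <- rnorm(n)
    zb <- rnorm(n)
    y <- 0.5 * group + 0.2 * za + rnorm(n)
    res <- cilp_test_regression(y, group, za, zb)

    X <- cbind(1, group, za, zb)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    resid <- y - X %*% beta
    sigma2 <- sum(resid^2) / (n - 4)
    se <- sqrt(sigma2 * diag(solve(t(X) %*% X)))
    p_oracle <- 2 * pt(abs(beta / se), df = n - 4, lower.tail = FALSE)
    expect_equal(res$p_group, p_oracle[2], tolerance = 1e-10)
    expect_equal(res$p_cov_a, p_oracle[3], tolerance = 1e-10)
    expect_equal(res$p_cov_b, p_oracle[4], tolerance = 1e-10)
    expect_equal(unname(res$beta), as.vector(beta), tolerance = 1e-10)

    # strong planted group effect
    n2 <- 200
    g2 <- rep(c(0, 1), each = n2 / 2)
    y2 <- 2 * g2 + rnorm(n2, sd = 0.1)
    strong <- cilp_test_regression(y2, g2, rnorm(n2), rnorm(n2))
    expect_lt(strong$p_group, 1e-10)

    # rank-deficient design refused
    expect_error(cilp_test_regression(y, group, za, za), "singular")
  })
})

test_that("BH adjustment follows the step-up rule and its invariances", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(13, {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
    perm <- sample(50)
    expect_equal(bh_fdr(p[perm])[order(perm)], q)  # permutation invariant
  })
})

test_that("DCL calling thresholds the family-wise FDR and sorts by p", {
  res <- data.frame(gene_a = c("a", "c", "e"), gene_b = c("b", "d", "f"),
                    p_group = c(0.5, 0.01, 0.2))
  res$fdr_group <- bh_fdr(res$p_group)
  expect_equal(nrow(call_dcls(res, fdr_cutoff = 0)), 0)
  one <- data.frame(gene_a = "a", gene_b = "b", p_group = 0.01,
                    fdr_group = bh_fdr(0.01))
  expect_equal(nrow(call_dcls(one, 0.3)), 1)
  called <- call_dcls(res, 0.3)
  expect_false(is.unsorted(called$p_group))
  expect_true(all(called$is_dcl))
})

test_that("DE-dependence splits on the pooled covariate FDR", {
  res <- data.frame(fdr_cov_a = c(1, 0.001, 0.5),
                    fdr_cov_b = c(1, 0.9, 0.05))
  lab <- classify_de_dependence(res, fdr_cutoff = 0.1)$de_dependence
  expect_equal(as.character(lab),
               c("DE-independent", "DE-dependent", "DE-dependent"))

  # planted product-expression dependence: products loading linearly on the
  # gene-a covariate are flagged DE-dependent in the vast majority of runs
  withr::with_seed(41, {
    hits <- 0
    n_rep <- 20
    for (rep in seq_len(n_rep)) {
      n <- 120
      group <- rep(c(0, 1), each = n / 2)
      za <- rnorm(n)
      zb <- rnorm(n)
      y <- 0.5 * za + rnorm(n, sd = 0.5)   # depends on gene a, not on group
      fit <- cilp_test_regression(y, group, za, zb)
      if (min(fit$p_cov_a, fit$p_cov_b) < 0.1) hits <- hits + 1
    }
    expect_gte(hits / n_rep, 0.8)
  })
})
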