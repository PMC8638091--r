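#' Z-score genes across samples
#'
#' Centers and scales each gene row to mean 0 and sample standard deviation 1
#' (denominator n - 1). On z-scored rows the Pearson correlation of two genes
#' equals the sum of their per-sample products divided by n - 1, which is the
#' identity the sample-wise product-correlation (CILP) statistic rests on.
#'
#' Zero-variance genes cannot be scaled; they are dropped from the result and
#' listed in the `"excluded"` attribute so callers can report them.
#'
#' @param m Numeric genes x samples matrix.
#' @return Matrix of z-scored rows, possibly with fewer rows than the input;
#'   `attr(, "excluded")` holds the ids of zero-variance genes (character(0)
#'   if none).
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' z <- zscore_genes(m)   # g2 is constant and gets excluded
#' attr(z, "excluded")
#' @export
zscore_genes <- function(m) {
  check_expression_matrix(m)
  if (ncol(m) < 2) stop("need >= 2 samples to z-score", call. = FALSE)
  mu <- rowMeans(m)
  centered <- m - mu
  sds <- sqrt(rowSums(centered^2) / (ncol(m) - 1))
  bad <- sds == 0 | !is.finite(sds)
  z <- centered[!bad, , drop = FALSE] / sds[!bad]
  attr(z, "excluded") <- rownames(m)[bad]
  z
}

#' Per-sample product correlations of a gene pair
#'
#' The elementwise product of two z-scored expression vectors. Each entry is
#' that sample's contribution to the Pearson correlation: the products sum to
#' (n - 1) times the correlation coefficient.
#'
#' @param z_a,z_b Z-scored expression vectors of equal length (>= 3).
#' @return Numeric vector of per-sample products.
#' @export
product_correlation <- function(z_a, z_b) {
  if (length(z_a) != length(z_b)) {
    stop("vectors differ in length: ", length(z_a), " vs ", length(z_b),
         call. = FALSE)
  }
  if (length(z_a) < 3) stop("need >= 3 samples", call. = FALSE)
  z_a * z_b
}

#' Product-correlation records for a list of gene pairs
#'
#' For each pair, z-scores the two genes within each condition, forms the
#' per-sample products, and records the condition-wise Pearson correlations.
#' Pairs touching a zero-variance gene in either condition are dropped and
#' reported via the `"rejected"` attribute.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param normal,tumor Genes x samples matrices (log scale).
#' @return List with `pairs` (the retained pair table with `pcc_normal`,
#'   `pcc_tumor`), `products_normal` and `products_tumor` (pairs x samples
#'   matrices of per-sample products, rownames = pair keys), `z_normal`,
#'   `z_tumor` (z-scored expression), and attribute-style element `rejected`
#'   (pair table of excluded pairs with a `reason`).
#' @export
product_correlation_records <- function(pairs, normal, tumor) {
  check_pairs(pairs)
  check_pair_genes(pairs, normal, "normal")
  check_pair_genes(pairs, tumor, "tumor")
  zn <- zscore_genes(normal)
  zt <- zscore_genes(tumor)
  excluded <- union(attr(zn, "excluded"), attr(zt, "excluded"))
  bad <- pairs$gene_a %in% excluded | pairs$gene_b %in% excluded
  rejected <- pairs[bad, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- "zero-variance gene"
  keep <- pairs[!bad, , drop = FALSE]
  pn <- zn[keep$gene_a, , drop = FALSE] * zn[keep$gene_b, , drop = FALSE]
  pt <- zt[keep$gene_a, , drop = FALSE] * zt[keep$gene_b, , drop = FALSE]
  keys <- pair_key(keep$gene_a, keep$gene_b)
  rownames(pn) <- keys
  rownames(pt) <- keys
  keep$pcc_normal <- rowSums(pn) / (ncol(pn) - 1)
  keep$pcc_tumor <- rowSums(pt) / (ncol(pt) - 1)
  list(pairs = keep, products_normal = pn, products_tumor = pt,
       z_normal = zn, z_tumor = zt, rejected = rejected)
}

#' Paired CILP test for one gene pair
#'
#' Two-sided paired t-test on per-subject differences of product correlations
#' (tumor minus normal). With one product value per subject and condition the
#' regression of products on the group indicator degenerates to exactly this
#' test.
#'
#' Zero-variance nonzero differences make the t statistic infinite; the
#' p-value is then set to the smallest positive double and flagged degenerate
#' rather than dropped.
#'
#' @param products_normal,products_tumor Per-subject product values aligned on
#'   the same subject order (length >= 3).
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
cilp_test_paired <- function(products_normal, products_tumor) {
  if (length(products_normal) != length(products_tumor)) {
    stop("paired product vectors differ in length", call. = FALSE)
  }
  n <- length(products_normal)
  if (n < 3) stop("need >= 3 complete subject pairs", call. = FALSE)
  d <- products_tumor - products_normal
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(list(t = 0, df = n - 1, p = 1, mean_diff = 0, degenerate = FALSE))
    }
    return(list(t = sign(md) * Inf, df = n - 1, p = .Machine$double.xmin,
                mean_diff = md, degenerate = TRUE))
  }
  tstat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  list(t = tstat, df = n - 1, p = p, mean_diff = md, degenerate = FALSE)
}

# vectorized paired t-test over rows of two aligned pairs x subjects matrices
paired_t_rows <- function(P_normal, P_tumor) {
  n <- ncol(P_normal)
  D <- P_tumor - P_normal
  md <- rowMeans(D)
  sdd <- sqrt(rowSums((D - md)^2) / (n - 1))
  tstat <- md / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  degenerate <- sdd == 0 & md != 0
  p[degenerate] <- .Machine$double.xmin
  p[sdd == 0 & md == 0] <- 1
  tstat[sdd == 0 & md == 0] <- 0
  list(t = tstat, p = p, mean_diff = md, degenerate = degenerate)
}

#' Regression CILP test for one gene pair
#'
#' Ordinary least squares of the stacked product-correlation values on an
#' intercept, the binary group indicator, and the z-scored expression of the
#' two genes. Two-sided t-tests on the coefficients give the group-effect
#' p-value (differential coexpression) and the two covariate p-values
#' (dependence of the products on either gene's expression, used to separate
#' DE-dependent from DE-independent links).
#'
#' @param products Stacked product values across both conditions.
#' @param group Binary indicator (0 = normal, 1 = tumor), same length.
#' @param z_a,z_b Z-scored expression covariates of the two genes, stacked in
#'   the same sample order.
#' @return List with `p_group`, `p_cov_a`, `p_cov_b`, coefficient estimates
#'   `beta` (named), and residual degrees of freedom `df`.
#' @export
cilp_test_regression <- function(products, group, z_a, z_b) {
  n <- length(products)
  if (length(group) != n || length(z_a) != n || length(z_b) != n) {
    stop("products, group and covariates must have equal length", call. = FALSE)
  }
  X <- cbind(intercept = 1, group = as.numeric(group), z_a = z_a, z_b = z_b)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("singular design matrix in regression CILP test", call. = FALSE)
  }
  fit <- stats::lm.fit(X, products)
  df <- n - ncol(X)
  if (df < 1) stop("not enough samples for the regression test", call. = FALSE)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- fit$coefficients / se
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  list(p_group = unname(p["group"]), p_cov_a = unname(p["z_a"]),
       p_cov_b = unname(p["z_b"]), beta = fit$coefficients, df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment of a p-value family to false-discovery-rate q-values,
#' with monotonicity enforced (wraps [stats::p.adjust()] with `method = "BH"`
#' after validating the input domain).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Paired CILP analysis over a pair list
#'
#' Runs the paired differential-coexpression test for every pair: per-sample
#' products are computed within each condition (z-scoring per condition), the
#' per-subject product differences are tested with a paired t-test, and the
#' group p-values are BH-adjusted over the family of all tested pairs.
#'
#' Columns of `normal` and `tumor` must be aligned so that column i of each
#' matrix belongs to the same subject (the paired design).
#'
#' @inheritParams product_correlation_records
#' @return data.frame with one row per retained pair: `gene_a`, `gene_b`,
#'   `pcc_normal`, `pcc_tumor`, `t`, `mean_diff`, `p_group`, `fdr_group`,
#'   `degenerate`; the rejected-pair report is in `attr(, "rejected")`.
#' @export
cilp_paired <- function(pairs, normal, tumor) {
  if (ncol(normal) != ncol(tumor)) {
    stop("paired analysis needs equal sample counts per condition",
         call. = FALSE)
  }
  if (ncol(normal) < 3) stop("need >= 3 complete subject pairs", call. = FALSE)
  rec <- product_correlation_records(pairs, normal, tumor)
  res <- rec$pairs
  if (nrow(res) > 0) {
    tt <- paired_t_rows(rec$products_normal, rec$products_tumor)
    res$t <- tt$t
    res$mean_diff <- tt$mean_diff
    res$p_group <- tt$p
    res$degenerate <- tt$degenerate
  } else {
    res$t <- numeric(0)
    res$mean_diff <- numeric(0)
    res$p_group <- numeric(0)
    res$degenerate <- logical(0)
  }
  res$fdr_group <- bh_fdr(res$p_group)
  attr(res, "rejected") <- rec$rejected
  res
}

#' Regression CILP analysis over a pair list
#'
#' Runs the covariate-adjusted differential-coexpression test for every pair:
#' stacked product correlations are regressed on the group indicator plus the
#' z-scored expression of both genes. Suitable for non-paired designs and for
#' classifying links as DE-dependent or DE-independent. Group p-values are
#' BH-adjusted over all tested pairs; the two covariate p-value columns are
#' BH-adjusted over the single pooled family of all covariate p-values.
#'
#' @inheritParams product_correlation_records
#' @return data.frame with `gene_a`, `gene_b`, `pcc_normal`, `pcc_tumor`,
#'   `p_group`, `fdr_group`, `p_cov_a`, `p_cov_b`, `fdr_cov_a`, `fdr_cov_b`;
#'   rejected pairs in `attr(, "rejected")`.
#' @export
cilp_regression <- function(pairs, normal, tumor) {
  if (ncol(normal) < 3 || ncol(tumor) < 3) {
    stop("need >= 3 samples per condition", call. = FALSE)
  }
  rec <- product_correlation_records(pairs, normal, tumor)
  res <- rec$pairs
  group <- c(rep(0, ncol(normal)), rep(1, ncol(tumor)))
  np <- nrow(res)
  p_group <- p_a <- p_b <- numeric(np)
  for (i in seq_len(np)) {
    products <- c(rec$products_normal[i, ], rec$products_tumor[i, ])
    za <- c(rec$z_normal[res$gene_a[i], ], rec$z_tumor[res$gene_a[i], ])
    zb <- c(rec$z_normal[res$gene_b[i], ], rec$z_tumor[res$gene_b[i], ])
    fit <- cilp_test_regression(products, group, za, zb)
    p_group[i] <- fit$p_group
    p_a[i] <- fit$p_cov_a
    p_b[i] <- fit$p_cov_b
  }
  res$p_group <- p_group
  res$fdr_group <- bh_fdr(p_group)
  res$p_cov_a <- p_a
  res$p_cov_b <- p_b
  pooled <- bh_fdr(c(p_a, p_b))
  res$fdr_cov_a <- pooled[seq_len(np)]
  res$fdr_cov_b <- pooled[np + seq_len(np)]
  attr(res, "rejected") <- rec$rejected
  res
}

#' Call differentially coexpressed links (DCLs)
#'
#' Flags pairs whose group-effect FDR is at or below the cutoff and returns
#' the flagged subset sorted by increasing group p-value. The FDR must have
#' been computed over the family of all pairs tested in the run (as
#' [cilp_paired()] and [cilp_regression()] do).
#'
#' @param results data.frame with columns `p_group` and `fdr_group`.
#' @param fdr_cutoff FDR threshold; the permissive pan-cancer screen uses 0.3,
#'   the stricter reproducibility analysis 0.1.
#' @return The input rows with `is_dcl = TRUE`, sorted by `p_group`.
#' @export
call_dcls <- function(results, fdr_cutoff = 0.3) {
  if (!all(c("p_group", "fdr_group") %in% names(results))) {
    stop("'results' must contain p_group and fdr_group", call. = FALSE)
  }
  results$is_dcl <- results$fdr_group <= fdr_cutoff
  out <- results[results$is_dcl, , drop = FALSE]
  out[order(out$p_group), , drop = FALSE]
}

#' Classify DCLs as DE-dependent or DE-independent
#'
#' A link is DE-dependent when its product correlations show significant
#' dependence on at least one gene's expression: min of the two covariate
#' FDRs below the cutoff, with the covariate FDR adjusted over the pooled
#' family of all covariate p-values from all tested pairs.
#'
#' @param results data.frame from [cilp_regression()] (needs `fdr_cov_a`,
#'   `fdr_cov_b`).
#' @param fdr_cutoff Covariate-significance threshold, default 0.1.
#' @return `results` with a `de_dependence` factor column
#'   (`"DE-dependent"` / `"DE-independent"`).
#' @export
classify_de_dependence <- function(results, fdr_cutoff = 0.1) {
  if (!all(c("fdr_cov_a", "fdr_cov_b") %in% names(results))) {
    stop("'results' must contain fdr_cov_a and fdr_cov_b", call. = FALSE)
  }
  dep <- pmin(results$fdr_cov_a, results$fdr_cov_b) < fdr_cutoff
  results$de_dependence <- factor(ifelse(dep, "DE-dependent", "DE-independent"),
                                  levels = c("DE-dependent", "DE-independent"))
  results
}
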