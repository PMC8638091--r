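#' Rank genes by differential expression
#'
#' Per-gene paired (or Welch) t-test between conditions, converted to a
#' signed ranking score: `sign(mean tumor - mean normal) * -log10(p)`. The
#' returned list is sorted by decreasing score, with ties broken
#' deterministically by gene id, and is the ranking consumed by preranked
#' enrichment (the RNK convention).
#'
#' Zero-variance genes yield a degenerate p-value (smallest positive double
#' when the mean shift is nonzero, 1 when it is zero) and are flagged.
#'
#' @param normal,tumor Genes x samples matrices over the same genes; for
#'   `paired = TRUE` columns must be subject-aligned with equal counts.
#' @param paired Use a paired t-test (default) or Welch's two-sample test.
#' @return data.frame sorted by rank: `gene_id`, `score`, `p`, `rank`,
#'   `degenerate`.
#' @export
rank_genes_by_de <- function(normal, tumor, paired = TRUE) {
  check_expression_matrix(normal)
  check_expression_matrix(tumor)
  if (!identical(rownames(normal), rownames(tumor))) {
    stop("'normal' and 'tumor' must cover the same genes in the same order",
         call. = FALSE)
  }
  if (ncol(normal) < 3 || ncol(tumor) < 3) {
    stop("need >= 3 samples per condition", call. = FALSE)
  }
  shift <- rowMeans(tumor) - rowMeans(normal)
  if (paired) {
    if (ncol(normal) != ncol(tumor)) {
      stop("paired test needs equal sample counts", call. = FALSE)
    }
    D <- tumor - normal
    n <- ncol(D)
    md <- rowMeans(D)
    sdd <- sqrt(rowSums((D - md)^2) / (n - 1))
    tstat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
    degenerate <- sdd == 0
  } else {
    n1 <- ncol(normal); n2 <- ncol(tumor)
    v1 <- apply(normal, 1, stats::var)
    v2 <- apply(tumor, 1, stats::var)
    se2 <- v1 / n1 + v2 / n2
    tstat <- shift / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
    degenerate <- se2 == 0
  }
  p[degenerate & shift != 0] <- .Machine$double.xmin
  p[degenerate & shift == 0] <- 1
  score <- sign(shift) * -log10(p)
  score[shift == 0] <- 0
  out <- data.frame(gene_id = rownames(normal), score = score, p = p,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("gene_id", "score", "p", "rank", "degenerate")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down a ranked gene list accumulating a running sum: genes in the set
#' add increments proportional to `|score|^weight` (normalized so hits sum to
#' 1), genes outside subtract `1/(G - set size)`. The enrichment score is the
#' maximum deviation of the running sum from zero, signed by its direction —
#' positive when the set concentrates at the top of the ranking, negative at
#' the bottom. `weight = 0` reduces to the classic Kolmogorov-Smirnov
#' statistic; `weight = 1` is the standard preranked setting.
#'
#' @param ranked data.frame from [rank_genes_by_de()] (needs `gene_id`,
#'   `score`, sorted by rank).
#' @param gene_set Character vector of gene ids, a proper nonempty subset of
#'   the ranked genes.
#' @param weight Nonnegative exponent on `|score|`; default 1.
#' @return Signed enrichment score in \[-1, 1\].
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- ranked$gene_id
  G <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0 || nh == G) {
    stop("gene set must be a nonempty proper subset of the ranked genes",
         call. = FALSE)
  }
  if (!all(gene_set %in% genes)) {
    stop("gene set members absent from ranking: ",
         paste(setdiff(gene_set, genes), collapse = ", "), call. = FALSE)
  }
  w <- abs(ranked$score)^weight
  denom_hit <- sum(w[hit])
  inc <- numeric(G)
  if (denom_hit == 0) {
    # all-zero scores: fall back to unweighted hit increments
    inc[hit] <- 1 / nh
  } else {
    inc[hit] <- w[hit] / denom_hit
  }
  inc[!hit] <- -1 / (G - nh)
  running <- cumsum(inc)
  i <- which.max(abs(running))
  running[i]
}

#' Permutation p-value for a gene-set enrichment score
#'
#' Two-sided gene-label permutation test: the observed score is compared with
#' scores of `n_perm` random gene sets of the same size, and
#' `p = (1 + #{|es*| >= |es|}) / (n_perm + 1)`, so the attainable minimum is
#' `1/(n_perm + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of random sets (>= 100).
#' @param seed Optional integer for a reproducible permutation stream.
#' @return List with `es`, `p`, `n_perm`, `set_size`.
#' @export
permutation_pvalue <- function(ranked, gene_set, n_perm = 1000, weight = 1,
                               seed = NULL) {
  if (n_perm < 100) stop("'n_perm' must be >= 100", call. = FALSE)
  es <- enrichment_score(ranked, gene_set, weight)
  size <- sum(ranked$gene_id %in% gene_set)
  draw <- function() {
    vapply(seq_len(n_perm), function(i) {
      rs <- sample(ranked$gene_id, size)
      enrichment_score(ranked, rs, weight)
    }, numeric(1))
  }
  null_es <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  list(es = es, p = p, n_perm = n_perm, set_size = size)
}

#' Write a ranked gene list in RNK format
#'
#' Two-column tab-separated file (gene id, signed score), sorted by
#' decreasing score, no header — the conventional input of preranked
#' enrichment tools.
#'
#' @param ranked data.frame from [rank_genes_by_de()].
#' @param path Output file path.
#' @export
write_rnk <- function(ranked, path) {
  utils::write.table(ranked[, c("gene_id", "score")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
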