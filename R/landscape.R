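#' Condition-wise Pearson correlations for a pair list
#'
#' Computes the Pearson correlation of each gene pair separately in the
#' normal and the tumor matrix, labels each pair Strengthened or Weakened by
#' the change in absolute correlation, and classifies its sign pattern.
#'
#' Labels: Strengthened iff `|pcc_tumor| > |pcc_normal|` (strictly); ties
#' count as Weakened, which is conservative with respect to claims of
#' correlation attenuation in tumors. Sign pattern compares the signs of the
#' two correlations (`differently signed`, `same-signed positive`,
#' `same-signed negative`); a correlation of exactly 0 is treated as
#' positive.
#'
#' @inheritParams product_correlation_records
#' @return data.frame with `gene_a`, `gene_b`, `pcc_normal`, `pcc_tumor`,
#'   `strength_change`, `sign_pattern`; pairs involving a zero-variance gene
#'   are excluded and reported in `attr(, "rejected")`.
#' @export
condition_pccs <- function(pairs, normal, tumor) {
  rec <- product_correlation_records(pairs, normal, tumor)
  out <- rec$pairs
  out$strength_change <- strength_labels(out$pcc_normal, out$pcc_tumor)
  out$sign_pattern <- sign_pattern_labels(out$pcc_normal, out$pcc_tumor)
  attr(out, "rejected") <- rec$rejected
  out
}

#' Build a labeled pair-correlation table from precomputed correlations
#'
#' Constructor for the table [condition_pccs()] produces, for workflows where
#' the condition-wise correlations are already available: attaches the
#' Strengthened/Weakened label and the sign-pattern class.
#'
#' @param gene_a,gene_b Gene ids of each pair.
#' @param pcc_normal,pcc_tumor Pearson correlations per pair and condition.
#' @return data.frame with the same columns as [condition_pccs()].
#' @export
pair_correlation_table <- function(gene_a, gene_b, pcc_normal, pcc_tumor) {
  n <- length(gene_a)
  if (length(gene_b) != n || length(pcc_normal) != n || length(pcc_tumor) != n) {
    stop("all arguments must have equal length", call. = FALSE)
  }
  if (any(abs(c(pcc_normal, pcc_tumor)) > 1 + 1e-8)) {
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  }
  data.frame(gene_a = gene_a, gene_b = gene_b, pcc_normal = pcc_normal,
             pcc_tumor = pcc_tumor,
             strength_change = strength_labels(pcc_normal, pcc_tumor),
             sign_pattern = sign_pattern_labels(pcc_normal, pcc_tumor),
             stringsAsFactors = FALSE)
}

strength_labels <- function(pcc_normal, pcc_tumor) {
  factor(ifelse(abs(pcc_tumor) > abs(pcc_normal), "Strengthened", "Weakened"),
         levels = c("Strengthened", "Weakened"))
}

sign_pattern_labels <- function(pcc_normal, pcc_tumor) {
  # sign 0 treated as positive (near-measure-zero for continuous data)
  pos_n <- pcc_normal >= 0
  pos_t <- pcc_tumor >= 0
  out <- ifelse(pos_n != pos_t, "differently signed",
                ifelse(pos_n, "same-signed positive", "same-signed negative"))
  factor(out, levels = c("differently signed", "same-signed positive",
                         "same-signed negative"))
}

#' Strengthened / Weakened fractions
#'
#' @param tbl A pair-correlation table from [condition_pccs()].
#' @return Named numeric vector `c(strengthened =, weakened =)`, summing to 1.
#' @export
strength_fractions <- function(tbl) {
  if (nrow(tbl) == 0) stop("empty pair table: fractions undefined", call. = FALSE)
  s <- mean(tbl$strength_change == "Strengthened")
  c(strengthened = s, weakened = 1 - s)
}

#' Cross-condition correlation regression
#'
#' Ordinary least squares of tumor correlations on normal correlations across
#' all pairs. A slope below 1 is the signature of global coexpression
#' attenuation in tumors.
#'
#' @param tbl A pair-correlation table with `pcc_normal`, `pcc_tumor`.
#' @return Named vector `c(slope =, intercept =)`.
#' @export
fit_cross_condition_slope <- function(tbl) {
  x <- tbl$pcc_normal
  y <- tbl$pcc_tumor
  if (length(unique(x)) < 2) {
    stop("degenerate regressor: need >= 2 distinct normal correlations",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  c(slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]))
}

#' Enumerate all unordered gene pairs
#'
#' All `n(n-1)/2` pairs of a gene id vector, in lexicographic index order
#' ((1,2), (1,3), ..., (n-1,n)).
#'
#' @param genes Character vector of gene ids.
#' @return data.frame with columns `gene_a`, `gene_b` (empty for < 2 genes).
#' @export
all_gene_pairs <- function(genes) {
  n <- length(genes)
  if (n < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  }
  idx_a <- rep.int(seq_len(n - 1), times = (n - 1):1)
  idx_b <- sequence((n - 1):1, from = 2:n)
  data.frame(gene_a = genes[idx_a], gene_b = genes[idx_b],
             stringsAsFactors = FALSE)
}

#' Half-thresholding candidate pair selection
#'
#' Among all pairs of the supplied genes, keeps the union of the pairs whose
#' absolute correlation ranks within the top fraction in the normal condition
#' and those ranking within the top fraction in the tumor condition ("half"
#' thresholding: a pair survives if it is strong in either condition). The
#' cutoff count is `ceiling(top_fraction * M)` over `M = n(n-1)/2` candidate
#' pairs; ties at the boundary are all admitted.
#'
#' @param genes Gene ids (>= 2) present in both matrices.
#' @inheritParams product_correlation_records
#' @param top_fraction Fraction in (0, 1]; default 0.01, the top-1% rule.
#' @return Pair-correlation table (as [condition_pccs()]) restricted to the
#'   selected pairs.
#' @export
half_threshold_pairs <- function(genes, normal, tumor, top_fraction = 0.01) {
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("'top_fraction' must be in (0, 1]", call. = FALSE)
  }
  pairs <- all_gene_pairs(genes)
  if (nrow(pairs) == 0) return(condition_pccs(pairs, normal, tumor))
  tbl <- condition_pccs(pairs, normal, tumor)
  M <- nrow(tbl)
  k <- ceiling(top_fraction * M)
  keep_top <- function(absval) {
    cutoff <- sort(absval, decreasing = TRUE)[min(k, M)]
    absval >= cutoff     # boundary ties all admitted
  }
  sel <- keep_top(abs(tbl$pcc_normal)) | keep_top(abs(tbl$pcc_tumor))
  out <- tbl[sel, , drop = FALSE]
  attr(out, "rejected") <- attr(tbl, "rejected")
  out
}

#' Asymmetric cross-condition correlation heatmap matrix
#'
#' Square matrix over an ordered gene list with normal-condition correlations
#' in the lower triangle, tumor-condition correlations in the upper triangle,
#' and 1 on the diagonal; rows and columns share the same gene order. This is
#' the matrix behind cross-conditional correlation heatmaps in which
#' symmetric off-diagonal positions show the same pair under the two
#' phenotypes.
#'
#' @param genes Ordered gene ids present in both matrices.
#' @inheritParams product_correlation_records
#' @return k x k numeric matrix with `genes` as dimnames.
#' @export
asymmetric_heatmap_matrix <- function(genes, normal, tumor) {
  missing <- setdiff(genes, intersect(rownames(normal), rownames(tumor)))
  if (length(missing) > 0) {
    stop("genes absent from an input matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cn <- stats::cor(t(normal[genes, , drop = FALSE]))
  ct <- stats::cor(t(tumor[genes, , drop = FALSE]))
  out <- cn
  out[upper.tri(out)] <- ct[upper.tri(ct)]
  diag(out) <- 1
  dimnames(out) <- list(genes, genes)
  out
}
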