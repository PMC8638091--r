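#' @keywords internal
"_PACKAGE"

# canonical string key for a gene pair, order-sensitive (pair lists keep
# their stated orientation; use pair_key(sort = TRUE) for set semantics)
pair_key <- function(gene_a, gene_b, sort = FALSE) {
  if (sort) {
    swap <- gene_a > gene_b
    tmp <- gene_a[swap]
    gene_a[swap] <- gene_b[swap]
    gene_b[swap] <- tmp
  }
  paste(gene_a, gene_b, sep = "|")
}

check_expression_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("'%s' must be a numeric matrix (genes x samples)", arg),
         call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(sprintf("'%s' must have gene rownames and sample colnames", arg),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    dup <- unique(rownames(m)[duplicated(rownames(m))])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    dup <- unique(colnames(m)[duplicated(colnames(m))])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(m)
}

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("gene_a", "gene_b") %in% names(pairs))) {
    stop("'pairs' must be a data.frame with columns gene_a and gene_b",
         call. = FALSE)
  }
  invisible(pairs)
}

# genes referenced by pairs but absent from a matrix -> error listing them
check_pair_genes <- function(pairs, m, label) {
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0) {
    stop(sprintf("genes absent from %s matrix: %s", label,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(pairs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a private RNG state seeded with `seed`, restoring the
# caller's generator afterwards; same seed => byte-identical draws
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
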