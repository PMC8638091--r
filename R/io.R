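# TSV dialect: tab-separated, UTF-8, '.' decimal, mandatory header row.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(basename(path), ": missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an expression matrix as TSV
#'
#' Rows are genes; the first column `gene_id` holds the gene identifiers and
#' the header carries the sample ids.
#'
#' @param m Genes x samples numeric matrix.
#' @param path Output file path.
#' @export
write_expression <- function(m, path) {
  check_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression matrix from TSV
#'
#' Expects the layout of [write_expression()]: a `gene_id` first column and
#' sample ids in the header. Duplicate ids and non-numeric cells are
#' itemized errors.
#'
#' @param path Input file path.
#' @return Genes x samples numeric matrix.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path, "gene_id")
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene ids in ", basename(path), ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, setdiff(names(df), "gene_id"), drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric expression columns in ", basename(path), ": ",
         paste(names(vals)[bad], collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(vals)
  rownames(m) <- df$gene_id
  check_expression_matrix(m)
  m
}

#' Read a gene-pair list from TSV
#'
#' @param path TSV with columns `gene_a`, `gene_b`.
#' @return data.frame of pairs; self-pairs and duplicate pairs are errors.
#' @export
read_pairs <- function(path) {
  df <- read_tsv(path, c("gene_a", "gene_b"))
  if (any(df$gene_a == df$gene_b)) {
    stop("self-pairs in ", basename(path), ": ",
         paste(df$gene_a[df$gene_a == df$gene_b], collapse = ", "),
         call. = FALSE)
  }
  keys <- pair_key(df$gene_a, df$gene_b, sort = TRUE)
  if (anyDuplicated(keys)) {
    stop("duplicate pairs in ", basename(path), ": ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a survival table from TSV
#'
#' @param path TSV with columns `subject_id`, `time`, `event`.
#' @return Validated data.frame; negative times, events outside \{0, 1\} and
#'   duplicate subjects are errors.
#' @export
read_survival <- function(path) {
  df <- read_tsv(path, c("subject_id", "time", "event"))
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject ids in ", basename(path), call. = FALSE)
  }
  if (!is.numeric(df$time) || any(is.na(df$time)) || any(df$time < 0)) {
    stop("survival times must be nonnegative numbers", call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  df
}

#' Read a sample-metadata table from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `condition`
#'   (values `normal` / `tumor`).
#' @return Validated data.frame.
#' @export
read_metadata <- function(path) {
  df <- read_tsv(path, c("sample_id", "subject_id", "condition"))
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in ", basename(path), call. = FALSE)
  }
  bad <- !df$condition %in% c("normal", "tumor")
  if (any(bad)) {
    stop("unknown condition values: ",
         paste(unique(df$condition[bad]), collapse = ", "), call. = FALSE)
  }
  df
}
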