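#' Log-transform an expression matrix
#'
#' Applies `log2(x + pseudocount)` elementwise. Raw abundance values
#' (counts or intensities) must be nonnegative.
#'
#' @param m Numeric genes x samples matrix with gene rownames and sample
#'   colnames.
#' @param pseudocount Positive offset added before taking logs; default 1 so
#'   that zero counts map to zero.
#' @return A matrix of the same shape on the log2 scale.
#' @examples
#' m <- matrix(c(0, 3, 1, 7), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' log_transform(m)
#' @export
log_transform <- function(m, pseudocount = 1) {
  check_expression_matrix(m)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("'pseudocount' must be a single positive number", call. = FALSE)
  }
  if (anyNA(m) || any(m < 0)) {
    stop("expression values must be nonnegative and non-missing for ",
         "log transformation", call. = FALSE)
  }
  out <- log2(m + pseudocount)
  dimnames(out) <- dimnames(m)
  out
}

#' Invert a log transformation
#'
#' Back-transforms `log_transform()` output to the raw scale:
#' `2^x - pseudocount`.
#'
#' @inheritParams log_transform
#' @return Matrix on the raw scale.
#' @export
unlog_transform <- function(m, pseudocount = 1) {
  check_expression_matrix(m)
  2^m - pseudocount
}

#' Quantile-normalize an expression matrix within a homogeneous group
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the value at each rank is replaced by the mean of that order statistic
#' across columns. Normalization is intended to be run separately per
#' homogeneous sample group (e.g. the normal matrix and the tumor matrix of
#' one cohort), never across conditions.
#'
#' Ties within a column receive the mean of the tied target quantiles
#' (the `ties = TRUE` convention of [limma::normalizeQuantiles()], which
#' performs the computation).
#'
#' @param m Numeric genes x samples matrix.
#' @return Matrix of the same shape; with a single column the input is
#'   returned unchanged with a warning.
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m)
  if (anyNA(m)) stop("missing values are not supported", call. = FALSE)
  if (ncol(m) < 2) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}
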