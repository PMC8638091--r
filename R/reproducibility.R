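#' Split samples into folds
#'
#' Randomly partitions sample ids into `k` disjoint folds. With
#' `target_size` given, folds 1..k-1 receive exactly `target_size` samples
#' and fold k the remainder (the scheme used to carve a large tumor cohort
#' into subsets matching the normal sample count); otherwise fold sizes
#' differ by at most 1.
#'
#' @param sample_ids Character vector of sample ids.
#' @param k Number of folds (>= 2).
#' @param target_size Optional exact size for the first k-1 folds.
#' @param seed Optional integer; when supplied the permutation is drawn from
#'   a locally seeded generator so the split is reproducible without
#'   disturbing the caller's RNG state.
#' @return data.frame with `sample_id` and `fold` (1..k);
#'   `attr(, "fold_sizes")` gives the size of each fold.
#' @export
split_folds <- function(sample_ids, k, target_size = NULL, seed = NULL) {
  n <- length(sample_ids)
  if (k < 2) stop("'k' must be >= 2", call. = FALSE)
  if (k > n) stop("more folds than samples", call. = FALSE)
  if (!is.null(target_size)) {
    if (target_size * (k - 1) >= n) {
      stop(sprintf("infeasible split: %d folds of %d exceed %d samples",
                   k - 1, target_size, n), call. = FALSE)
    }
    sizes <- c(rep(target_size, k - 1), n - target_size * (k - 1))
  } else {
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  }
  perm <- if (is.null(seed)) sample.int(n) else with_seed(seed, sample.int(n))
  fold <- rep(seq_len(k), times = sizes)
  out <- data.frame(sample_id = sample_ids[perm], fold = fold,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$sample_id, sample_ids)), ]
  rownames(out) <- NULL
  attr(out, "fold_sizes") <- sizes
  out
}

#' DCL recurrence across repeated analyses
#'
#' Counts, for each reference link, in how many of `k` repeated
#' differential-coexpression runs it was again called significant. When the
#' reference table carries `de_dependence` and `sign_pattern` columns the
#' counts can be stratified downstream into the six DE-dependence x
#' sign-pattern classes.
#'
#' @param reference_dcls data.frame of reference links (`gene_a`, `gene_b`,
#'   optionally `de_dependence`, `sign_pattern`).
#' @param run_dcl_sets List of k data.frames of links called in each run.
#' @return `reference_dcls` with an integer `recurrence` column in 0..k.
#' @export
recurrence_counts <- function(reference_dcls, run_dcl_sets) {
  check_pairs(reference_dcls)
  if (length(run_dcl_sets) < 1) stop("need >= 1 run", call. = FALSE)
  ref_keys <- pair_key(reference_dcls$gene_a, reference_dcls$gene_b, sort = TRUE)
  counts <- integer(length(ref_keys))
  for (run in run_dcl_sets) {
    check_pairs(run)
    run_keys <- pair_key(run$gene_a, run$gene_b, sort = TRUE)
    counts <- counts + as.integer(ref_keys %in% run_keys)
  }
  reference_dcls$recurrence <- counts
  reference_dcls
}

#' Recurrence histogram by stratum
#'
#' Tabulates recurrence counts within each DE-dependence x sign-pattern
#' stratum (the panel structure used to compare reproducibility of link
#' classes).
#'
#' @param recurrence data.frame from [recurrence_counts()] carrying
#'   `de_dependence` and `sign_pattern`.
#' @param k Number of repeated runs (histogram support 0..k).
#' @return data.frame with `de_dependence`, `sign_pattern`, `recurrence`,
#'   `n_links`.
#' @export
recurrence_histogram <- function(recurrence, k) {
  needed <- c("de_dependence", "sign_pattern", "recurrence")
  if (!all(needed %in% names(recurrence))) {
    stop("'recurrence' must contain ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(de_dependence = recurrence$de_dependence,
               sign_pattern = recurrence$sign_pattern,
               recurrence = factor(recurrence$recurrence, levels = 0:k))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out)[4] <- "n_links"
  out$recurrence <- as.integer(out$recurrence)
  out
}

#' Cross-fold concordance of pair correlations
#'
#' Pearson correlation matrix between per-fold vectors of gene-pair
#' correlations computed over a common pair list; high off-diagonal values
#' indicate that coexpression estimates are robust to the choice of sample
#' subset.
#'
#' @param pcc_vectors List of k numeric vectors, all of the same length and
#'   (if named) with identical pair names in identical order.
#' @return Symmetric k x k correlation matrix with unit diagonal.
#' @export
cross_fold_pcc_concordance <- function(pcc_vectors) {
  if (length(pcc_vectors) < 2) stop("need >= 2 folds", call. = FALSE)
  lens <- vapply(pcc_vectors, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("fold PCC vectors are not aligned on a common pair list", call. = FALSE)
  }
  nms <- lapply(pcc_vectors, names)
  has_names <- !vapply(nms, is.null, logical(1))
  if (any(has_names) && !all(has_names)) {
    stop("either all or none of the fold vectors must be named", call. = FALSE)
  }
  if (all(has_names)) {
    for (i in seq_along(nms)[-1]) {
      if (!identical(nms[[i]], nms[[1]])) {
        stop("fold PCC vectors are not aligned on a common pair list",
             call. = FALSE)
      }
    }
  }
  mat <- do.call(cbind, pcc_vectors)
  colnames(mat) <- names(pcc_vectors) %||% paste0("fold", seq_along(pcc_vectors))
  out <- stats::cor(mat)
  diag(out) <- 1
  out
}
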