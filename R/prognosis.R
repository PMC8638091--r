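#' Cohort-wide product correlations for survival screening
#'
#' For each differentially coexpressed link, derives one product-correlation
#' value per tumor sample across the survival cohort: subjects who
#' contributed paired samples to the link-discovery step are excluded, the
#' log-scale expression of each gene is centered and scaled across the
#' remaining tumor samples only, and the per-sample products of the two
#' z-scores are returned.
#'
#' @param tumor Genes x samples tumor expression matrix (log scale).
#' @param dcls data.frame of links with `gene_a`, `gene_b`.
#' @param exclude_samples Sample ids to drop before scaling (typically the
#'   tumor samples of normal-paired subjects); default none.
#' @return Pairs x samples matrix of product values (rownames = pair keys,
#'   colnames = retained sample ids). Links touching a zero-variance gene are
#'   dropped and listed in `attr(, "rejected")`.
#' @export
cohort_product_correlations <- function(tumor, dcls, exclude_samples = character(0)) {
  check_pairs(dcls)
  keep_samples <- setdiff(colnames(tumor), exclude_samples)
  if (length(keep_samples) == 0) {
    stop("all tumor samples excluded: empty survival cohort", call. = FALSE)
  }
  if (length(keep_samples) < 10) {
    stop("survival cohort too small (< 10 samples after exclusion)",
         call. = FALSE)
  }
  sub <- tumor[, keep_samples, drop = FALSE]
  check_pair_genes(dcls, sub, "tumor")
  z <- zscore_genes(sub)
  excluded <- attr(z, "excluded")
  bad <- dcls$gene_a %in% excluded | dcls$gene_b %in% excluded
  rejected <- dcls[bad, , drop = FALSE]
  keep <- dcls[!bad, , drop = FALSE]
  prod <- z[keep$gene_a, , drop = FALSE] * z[keep$gene_b, , drop = FALSE]
  rownames(prod) <- pair_key(keep$gene_a, keep$gene_b)
  attr(prod, "rejected") <- rejected
  prod
}

#' Median dichotomization
#'
#' Splits values at the across-cohort median: strictly above the median is
#' `"high"`, at or below is `"low"` (ties go to low, a deterministic rule).
#'
#' @param values Numeric vector, length >= 2.
#' @return Factor with levels `low`, `high`; if all values are identical the
#'   result is all `low` with attribute `degenerate = TRUE`.
#' @examples
#' dichotomize_by_median(c(1, 2, 3, 4))   # low low high high
#' dichotomize_by_median(c(1, 2, 2, 3))   # low low low high
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2) stop("need >= 2 values", call. = FALSE)
  med <- stats::median(values)
  out <- factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
  if (all(values == values[1])) attr(out, "degenerate") <- TRUE
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of overall survival between two groups: at
#' each distinct event time the observed number of deaths in one group is
#' compared with its hypergeometric expectation given the risk sets, the
#' observed-minus-expected differences are summed and scaled by the summed
#' variance, and the statistic is referred to a chi-square distribution with
#' one degree of freedom (computed via [survival::survdiff()]).
#'
#' @param time Nonnegative follow-up times.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param group Two-level grouping (factor or coercible), both levels present.
#' @return List with `chi_square`, `p`, `n` per group, `observed` and
#'   `expected` event counts per group, and `flag` (`"ok"` or
#'   `"zero-events"`).
#' @export
logrank_test <- function(time, event, group) {
  if (anyNA(time) || any(time < 0)) {
    stop("survival times must be nonnegative", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event indicator must be 0/1", call. = FALSE)
  }
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("log-rank test needs two nonempty groups", call. = FALSE)
  }
  if (sum(event) == 0) {
    n <- table(group)
    return(list(chi_square = 0, p = 1, n = n,
                observed = 0 * n, expected = 0 * n, flag = "zero-events"))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi <- unname(fit$chisq)
  lev <- levels(droplevels(group))
  list(chi_square = chi,
       p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       n = fit$n, observed = stats::setNames(as.vector(fit$obs), lev),
       expected = stats::setNames(as.vector(fit$exp), lev), flag = "ok")
}

#' Survival screen of differentially coexpressed links
#'
#' For every link, dichotomizes the cohort product-correlation values at the
#' median, runs the log-rank test of high- versus low-coexpression subjects
#' against overall survival, and BH-adjusts the p-values over the family of
#' all links screened in the run.
#'
#' @param products Pairs x samples product matrix from
#'   [cohort_product_correlations()].
#' @param surv data.frame with `subject_id`, `time`, `event`.
#' @param sample_subjects Named character vector mapping sample id (names) to
#'   subject id; defaults to identity (sample ids are subject ids). Samples
#'   without survival data, and subjects without expression, are dropped with
#'   a reported count.
#' @return data.frame with one row per link: `pair`, `n_high`, `n_low`,
#'   `chi_square`, `p`, `fdr`, `worse_group` (which coexpression group has
#'   more observed than expected deaths), `flag`; the number of unmatched
#'   samples is in `attr(, "n_unmatched")`.
#' @export
survival_screen <- function(products, surv, sample_subjects = NULL) {
  if (!all(c("subject_id", "time", "event") %in% names(surv))) {
    stop("'surv' must contain subject_id, time, event", call. = FALSE)
  }
  samples <- colnames(products)
  if (is.null(sample_subjects)) {
    sample_subjects <- stats::setNames(samples, samples)
  }
  subj <- unname(sample_subjects[samples])
  matched <- !is.na(subj) & subj %in% surv$subject_id
  n_unmatched <- sum(!matched)
  use <- samples[matched]
  subj <- subj[matched]
  if (length(use) < 2) stop("fewer than 2 samples with survival data", call. = FALSE)
  sv <- surv[match(subj, surv$subject_id), ]
  res <- data.frame(pair = rownames(products), n_high = NA_integer_,
                    n_low = NA_integer_, chi_square = NA_real_, p = NA_real_,
                    worse_group = NA_character_, flag = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(products))) {
    grp <- dichotomize_by_median(products[i, use])
    res$n_high[i] <- sum(grp == "high")
    res$n_low[i] <- sum(grp == "low")
    if (nlevels(droplevels(grp)) < 2) {
      res$chi_square[i] <- 0
      res$p[i] <- 1
      res$flag[i] <- "degenerate-split"
      next
    }
    lr <- logrank_test(sv$time, sv$event, grp)
    res$chi_square[i] <- lr$chi_square
    res$p[i] <- lr$p
    res$flag[i] <- lr$flag
    if (lr$flag == "ok") {
      excess <- lr$observed - lr$expected
      res$worse_group[i] <- names(excess)[which.max(excess)]
    }
  }
  res$fdr <- bh_fdr(res$p)
  attr(res, "n_unmatched") <- n_unmatched
  res
}

#' Call prognosis DCLs
#'
#' Flags links whose log-rank FDR is at or below the cutoff; these are the
#' conditional links whose coexpression level separates patients into groups
#' of significantly different overall survival.
#'
#' @param results data.frame from [survival_screen()].
#' @param fdr_cutoff FDR threshold, default 0.3.
#' @return Flagged subset with `is_prognosis_dcl = TRUE`, sorted by `p`.
#' @export
call_prognosis_dcls <- function(results, fdr_cutoff = 0.3) {
  if (!all(c("p", "fdr") %in% names(results))) {
    stop("'results' must contain p and fdr", call. = FALSE)
  }
  results$is_prognosis_dcl <- results$fdr <= fdr_cutoff
  out <- results[results$is_prognosis_dcl, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Kaplan-Meier curve coordinates for a dichotomized link
#'
#' Step-function coordinates of the Kaplan-Meier estimate per coexpression
#' group, for plotting survival separation of a prognosis link.
#'
#' @inheritParams logrank_test
#' @return data.frame with `group`, `time`, `surv`, `n_risk`, `n_event`.
#' @export
km_coordinates <- function(time, event, group) {
  group <- factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  data.frame(group = strata, time = fit$time, surv = fit$surv,
             n_risk = fit$n.risk, n_event = fit$n.event,
             stringsAsFactors = FALSE)
}
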