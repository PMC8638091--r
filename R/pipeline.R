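#' Pipeline configuration
#'
#' Validates thresholds and paths for [run_pipeline()].
#'
#' @param expression,metadata,pairs,survival Paths to the four TSV inputs
#'   (see [write_cohort()] for their layout).
#' @param out_dir Output directory for the stage TSVs and the run manifest.
#' @param dcl_fdr FDR cutoff accrediting differentially coexpressed links;
#'   default 0.3 (the permissive pan-cancer screen).
#' @param survival_fdr FDR cutoff for prognosis links; default 0.3.
#' @param de_dependence_fdr Covariate-FDR cutoff separating DE-dependent from
#'   DE-independent links; default 0.1.
#' @param half_threshold_fraction Top fraction for half-thresholding in the
#'   landscape stage; default 0.01.
#' @param min_matched_pairs Minimum number of subjects with both a normal and
#'   a tumor sample; cohorts below this are refused. Default 20.
#' @param log_transform Apply `log2(x + 1)` to the expression input (set
#'   `FALSE` when the input is already on the log scale).
#' @param quantile_normalize Quantile-normalize each condition's matrix
#'   within itself; default `TRUE`.
#' @param n_perm Permutations for the enrichment p-value; default 1000.
#' @param seed Integer seed for the pipeline's stochastic steps (enrichment
#'   permutations).
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, metadata, pairs, survival, out_dir,
                            dcl_fdr = 0.3, survival_fdr = 0.3,
                            de_dependence_fdr = 0.1,
                            half_threshold_fraction = 0.01,
                            min_matched_pairs = 20, log_transform = FALSE,
                            quantile_normalize = TRUE, n_perm = 1000,
                            seed = 1) {
  thr <- c(dcl_fdr = dcl_fdr, survival_fdr = survival_fdr,
           de_dependence_fdr = de_dependence_fdr,
           half_threshold_fraction = half_threshold_fraction)
  if (any(thr <= 0 | thr > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (min_matched_pairs < 3) stop("'min_matched_pairs' must be >= 3", call. = FALSE)
  structure(list(expression = expression, metadata = metadata, pairs = pairs,
                 survival = survival, out_dir = out_dir, dcl_fdr = dcl_fdr,
                 survival_fdr = survival_fdr,
                 de_dependence_fdr = de_dependence_fdr,
                 half_threshold_fraction = half_threshold_fraction,
                 min_matched_pairs = min_matched_pairs,
                 log_transform = log_transform,
                 quantile_normalize = quantile_normalize, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full differential-coexpression-to-prognosis analysis
#'
#' Executes the stages in order and writes every stage's table plus a JSON
#' run manifest:
#'
#' 1. **Read & preprocess** — load the four inputs, split the expression
#'    matrix by condition, optionally log-transform, quantile-normalize each
#'    condition within itself, and refuse cohorts with fewer matched
#'    normal/tumor subjects than `min_matched_pairs`.
#' 2. **Landscape** — condition-wise correlations for the pair list,
#'    Strengthened/Weakened fractions, and the cross-condition regression
#'    slope.
#' 3. **Differential coexpression** — paired CILP test per pair on the
#'    matched subjects, BH-FDR, DCL calling at `dcl_fdr`; a regression CILP
#'    run with expression covariates labels each DCL DE-dependent or
#'    DE-independent.
#' 4. **Prognosis** — cohort product correlations across tumor samples of
#'    subjects *not* in the paired set, median dichotomization, log-rank
#'    test, BH-FDR, prognosis-DCL calling at `survival_fdr`.
#' 5. **Enrichment** — paired t-test DE ranking of all genes and a
#'    permutation enrichment p-value for the set of DCL genes (DCGs),
#'    skipped (with a note) when fewer than 2 DCGs or no non-DCG genes
#'    remain.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with all stage tables and the manifest
#'   (`landscape`, `dc_results`, `dcls`, `prognosis`, `prognosis_dcls`,
#'   `de_ranking`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  expr <- read_expression(config$expression)
  meta <- read_metadata(config$metadata)
  pairs <- read_pairs(config$pairs)
  surv <- read_survival(config$survival)

  orphan <- setdiff(meta$sample_id, colnames(expr))
  if (length(orphan) > 0) {
    stop("metadata samples absent from expression matrix: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  normal_meta <- meta[meta$condition == "normal", ]
  tumor_meta <- meta[meta$condition == "tumor", ]
  matched_subjects <- intersect(normal_meta$subject_id, tumor_meta$subject_id)
  if (length(matched_subjects) < config$min_matched_pairs) {
    stop(sprintf(paste0("only %d matched normal/tumor subjects; at least %d ",
                        "are required for the paired analysis"),
                 length(matched_subjects), config$min_matched_pairs),
         call. = FALSE)
  }

  normal <- expr[, normal_meta$sample_id, drop = FALSE]
  tumor <- expr[, tumor_meta$sample_id, drop = FALSE]
  if (config$log_transform) {
    normal <- log_transform(normal)
    tumor <- log_transform(tumor)
  }
  if (config$quantile_normalize) {
    normal <- quantile_normalize(normal)
    tumor <- quantile_normalize(tumor)
  }

  # subject-aligned paired matrices for the matched subjects
  n_cols <- normal_meta$sample_id[match(matched_subjects, normal_meta$subject_id)]
  t_cols <- tumor_meta$sample_id[match(matched_subjects, tumor_meta$subject_id)]
  normal_p <- normal[, n_cols, drop = FALSE]
  tumor_p <- tumor[, t_cols, drop = FALSE]

  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)

  # landscape diagnostics over the supplied pair list
  landscape <- condition_pccs(pairs, normal_p, tumor_p)
  fractions <- strength_fractions(landscape)
  slope <- fit_cross_condition_slope(landscape)
  write_tsv(landscape, out("landscape.tsv"))

  # paired CILP differential-coexpression screen
  dc <- cilp_paired(pairs, normal_p, tumor_p)
  dcls <- call_dcls(dc, config$dcl_fdr)
  reg <- cilp_regression(pairs, normal_p, tumor_p)
  reg <- classify_de_dependence(reg, config$de_dependence_fdr)
  dep_map <- stats::setNames(as.character(reg$de_dependence),
                             pair_key(reg$gene_a, reg$gene_b))
  dc$de_dependence <- dep_map[pair_key(dc$gene_a, dc$gene_b)]
  dcls$de_dependence <- dep_map[pair_key(dcls$gene_a, dcls$gene_b)]
  write_tsv(dc, out("dc_results.tsv"))
  write_tsv(dcls, out("dcls.tsv"))

  # survival screen on tumor samples of non-paired subjects
  prognosis <- NULL
  prognosis_dcls <- NULL
  excluded_tumor <- tumor_meta$sample_id[tumor_meta$subject_id %in% matched_subjects]
  survival_cohort_size <- ncol(tumor) - length(excluded_tumor)
  if (nrow(dcls) > 0 && survival_cohort_size >= 10) {
    prods <- cohort_product_correlations(tumor, dcls,
                                         exclude_samples = excluded_tumor)
    sample_subjects <- stats::setNames(tumor_meta$subject_id,
                                       tumor_meta$sample_id)
    prognosis <- survival_screen(prods, surv, sample_subjects)
    prognosis_dcls <- call_prognosis_dcls(prognosis, config$survival_fdr)
    write_tsv(prognosis, out("prognosis.tsv"))
    write_tsv(prognosis_dcls, out("prognosis_dcls.tsv"))
  }

  # DE ranking and DCG enrichment
  de_ranking <- rank_genes_by_de(normal_p, tumor_p, paired = TRUE)
  write_rnk(de_ranking, out("de_ranking.rnk"))
  dcgs <- unique(c(dcls$gene_a, dcls$gene_b))
  enr <- NULL
  if (length(dcgs) >= 2 && length(dcgs) < nrow(de_ranking)) {
    enr <- permutation_pvalue(de_ranking, dcgs, n_perm = config$n_perm,
                              seed = config$seed)
  }

  manifest <- list(
    config = unclass(config),
    counts = list(
      genes = nrow(expr),
      samples_normal = ncol(normal),
      samples_tumor = ncol(tumor),
      matched_subjects = length(matched_subjects),
      pairs_tested = nrow(dc),
      pairs_rejected = nrow(attr(dc, "rejected") %||% data.frame()),
      dcls = nrow(dcls),
      dcgs = length(dcgs),
      survival_cohort = survival_cohort_size,
      prognosis_dcls = if (is.null(prognosis_dcls)) 0L else nrow(prognosis_dcls)
    ),
    landscape = list(fraction_strengthened = unname(fractions["strengthened"]),
                     fraction_weakened = unname(fractions["weakened"]),
                     slope = unname(slope["slope"]),
                     intercept = unname(slope["intercept"])),
    enrichment = if (is.null(enr)) NULL else enr
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(list(landscape = landscape, dc_results = dc, dcls = dcls,
                 prognosis = prognosis, prognosis_dcls = prognosis_dcls,
                 de_ranking = de_ranking, enrichment = enr,
                 manifest = manifest))
}
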