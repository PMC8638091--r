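#' Simulation configuration for a paired normal/tumor cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. The defaults
#' describe a mid-sized paired cohort: 60 subjects with both a normal and a
#' tumor sample, 200 additional unpaired tumor samples carrying survival
#' follow-up, and independent unit-variance Gaussian expression on the log
#' scale onto which coexpression, expression, and hazard effects are planted.
#'
#' @param n_subjects Number of paired subjects (normal + tumor sample each).
#' @param n_extra_tumor Number of unpaired tumor samples (the survival
#'   cohort, on top of the paired subjects' tumor samples).
#' @param n_genes Number of genes.
#' @param dc_pairs data.frame(`gene_a`, `gene_b`, `rho_normal`, `rho_tumor`)
#'   of planted differentially coexpressed pairs; genes must be distinct
#'   within and across planted pairs.
#' @param de_genes data.frame(`gene`, `lfc`) of planted differential
#'   expression: `lfc` is added to the gene's tumor values (log2 scale).
#' @param null_pairs Number of background pairs (correlation 0 in both
#'   conditions) appended to the pair list from genes not used by `dc_pairs`.
#' @param prognosis_pairs data.frame(`gene_a`, `gene_b`, `hazard_ratio`) of
#'   pairs whose above-median product correlation multiplies a subject's
#'   hazard by `hazard_ratio`.
#' @param baseline_hazard Exponential event rate per time unit for the
#'   low-coexpression group; default 0.002 (median survival around 350 time
#'   units).
#' @param censor_rate Probability that a subject is censored; default 0.3,
#'   typical of cancer cohorts with moderate follow-up.
#' @param noise_sd Standard deviation of the log-scale expression noise;
#'   default 1.
#' @param mean_log_expr Baseline log2 expression level; default 8.
#' @param seed Integer seed driving a single private generator.
#' @return Validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 60, n_extra_tumor = 200, n_genes = 100,
                       dc_pairs = NULL, de_genes = NULL, null_pairs = 0,
                       prognosis_pairs = NULL, baseline_hazard = 0.002,
                       censor_rate = 0.3, noise_sd = 1, mean_log_expr = 8,
                       seed = 1) {
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  empty_dc <- data.frame(gene_a = character(0), gene_b = character(0),
                         rho_normal = numeric(0), rho_tumor = numeric(0),
                         stringsAsFactors = FALSE)
  empty_de <- data.frame(gene = character(0), lfc = numeric(0),
                         stringsAsFactors = FALSE)
  empty_pg <- data.frame(gene_a = character(0), gene_b = character(0),
                         hazard_ratio = numeric(0), stringsAsFactors = FALSE)
  dc_pairs <- dc_pairs %||% empty_dc
  de_genes <- de_genes %||% empty_de
  prognosis_pairs <- prognosis_pairs %||% empty_pg
  if (n_subjects < 3) stop("'n_subjects' must be >= 3", call. = FALSE)
  if (n_extra_tumor < 0) stop("'n_extra_tumor' must be >= 0", call. = FALSE)
  if (any(abs(c(dc_pairs$rho_normal, dc_pairs$rho_tumor)) >= 1)) {
    stop("planted correlations must satisfy |rho| < 1", call. = FALSE)
  }
  if (any(prognosis_pairs$hazard_ratio <= 0)) {
    stop("hazard ratios must be positive", call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("'censor_rate' must be in [0, 1)", call. = FALSE)
  }
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be positive", call. = FALSE)
  if (noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  dc_genes <- c(dc_pairs$gene_a, dc_pairs$gene_b)
  if (anyDuplicated(dc_genes)) {
    stop("planted DC pairs must use distinct genes", call. = FALSE)
  }
  unknown <- setdiff(unique(c(dc_genes, de_genes$gene, prognosis_pairs$gene_a,
                              prognosis_pairs$gene_b)), gene_ids)
  if (length(unknown) > 0) {
    stop("configured gene ids not among the ", n_genes, " genes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pg_keys <- pair_key(prognosis_pairs$gene_a, prognosis_pairs$gene_b, sort = TRUE)
  known_keys <- pair_key(dc_pairs$gene_a, dc_pairs$gene_b, sort = TRUE)
  if (!all(pg_keys %in% known_keys)) {
    stop("prognosis pairs must be among the planted DC pairs", call. = FALSE)
  }
  free_genes <- setdiff(gene_ids, dc_genes)
  if (null_pairs > floor(length(free_genes) / 2)) {
    stop("not enough unused genes for ", null_pairs, " null pairs",
         call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, n_extra_tumor = n_extra_tumor,
                 n_genes = n_genes, gene_ids = gene_ids, dc_pairs = dc_pairs,
                 de_genes = de_genes, null_pairs = null_pairs,
                 prognosis_pairs = prognosis_pairs,
                 baseline_hazard = baseline_hazard, censor_rate = censor_rate,
                 noise_sd = noise_sd, mean_log_expr = mean_log_expr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Sample a correlated gene pair
#'
#' Draws `n` observations of two traits from a bivariate normal with zero
#' mean, unit variance, and population correlation `rho`, via the Cholesky
#' construction `y = rho * x + sqrt(1 - rho^2) * e`.
#'
#' @param rho Population correlation, |rho| < 1.
#' @param n Number of samples (>= 3).
#' @return n x 2 matrix; columns are the two traits.
#' @export
sample_pair_expression <- function(rho, n) {
  if (!is.numeric(rho) || length(rho) != 1 || abs(rho) >= 1) {
    stop("'rho' must satisfy |rho| < 1", call. = FALSE)
  }
  if (n < 3) stop("'n' must be >= 3", call. = FALSE)
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(x, y)
}

#' Generate a synthetic paired cohort with planted effects
#'
#' Builds paired normal/tumor expression matrices, sample metadata, a
#' survival table, and truth tables under a single seeded generator:
#'
#' * Background genes are independent Gaussians on the log2 scale
#'   (`mean_log_expr` + `noise_sd` * N(0,1)).
#' * Each planted DC pair's two genes are replaced by bivariate draws at
#'   `rho_normal` (normal samples) and `rho_tumor` (all tumor samples).
#' * Planted DE genes get `lfc` added to their tumor values.
#' * Each tumor sample's hazard is
#'   `baseline_hazard * prod(hazard_ratio ^ high_i)` where `high_i` indicates
#'   an above-median product correlation for prognosis pair i, z-scored
#'   across the whole tumor cohort; survival times are exponential with that
#'   rate, and with probability `censor_rate` a subject is censored uniformly
#'   before its event time.
#'
#' @param config A [sim_config()] object.
#' @return List of class `"synthetic_cohort"`: `expr_normal`, `expr_tumor`
#'   (genes x samples, log2 scale), `metadata` (sample_id, subject_id,
#'   condition), `survival` (subject_id, time, event), `pairs` (the planted +
#'   null pair list), and `truth` (dc_pairs, de_genes, prognosis_pairs).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_sub <- config$n_subjects
    n_tum <- n_sub + config$n_extra_tumor
    genes <- config$gene_ids
    subj_paired <- sprintf("sub%04d", seq_len(n_sub))
    subj_extra <- sprintf("sub%04d", n_sub + seq_len(config$n_extra_tumor))
    normal_ids <- paste0(subj_paired, "_N")
    tumor_ids <- c(paste0(subj_paired, "_T"),
                   paste0(subj_extra, "_T", recycle0 = TRUE))
    ngen <- config$n_genes

    expr_normal <- matrix(stats::rnorm(ngen * n_sub, 0, 1), ngen, n_sub)
    expr_tumor <- matrix(stats::rnorm(ngen * n_tum, 0, 1), ngen, n_tum)
    dimnames(expr_normal) <- list(genes, normal_ids)
    dimnames(expr_tumor) <- list(genes, tumor_ids)

    dc <- config$dc_pairs
    for (i in seq_len(nrow(dc))) {
      xy_n <- sample_pair_expression(dc$rho_normal[i], n_sub)
      xy_t <- sample_pair_expression(dc$rho_tumor[i], n_tum)
      expr_normal[dc$gene_a[i], ] <- xy_n[, 1]
      expr_normal[dc$gene_b[i], ] <- xy_n[, 2]
      expr_tumor[dc$gene_a[i], ] <- xy_t[, 1]
      expr_tumor[dc$gene_b[i], ] <- xy_t[, 2]
    }

    expr_normal <- config$mean_log_expr + config$noise_sd * expr_normal
    expr_tumor <- config$mean_log_expr + config$noise_sd * expr_tumor

    de <- config$de_genes
    for (i in seq_len(nrow(de))) {
      expr_tumor[de$gene[i], ] <- expr_tumor[de$gene[i], ] + de$lfc[i]
    }

    # background pair list from genes untouched by DC planting
    pairs <- dc[, c("gene_a", "gene_b")]
    if (config$null_pairs > 0) {
      free <- setdiff(genes, c(dc$gene_a, dc$gene_b))
      pick <- matrix(free[seq_len(2 * config$null_pairs)], ncol = 2)
      pairs <- rbind(pairs, data.frame(gene_a = pick[, 1], gene_b = pick[, 2],
                                       stringsAsFactors = FALSE))
    }
    rownames(pairs) <- NULL

    # hazard per tumor subject from dichotomized prognosis-pair products
    log_hazard <- rep(log(config$baseline_hazard), n_tum)
    pg <- config$prognosis_pairs
    if (nrow(pg) > 0) {
      z <- zscore_genes(expr_tumor)
      for (i in seq_len(nrow(pg))) {
        prods <- z[pg$gene_a[i], ] * z[pg$gene_b[i], ]
        high <- prods > stats::median(prods)
        log_hazard <- log_hazard + log(pg$hazard_ratio[i]) * high
      }
    }
    event_time <- stats::rexp(n_tum, rate = exp(log_hazard))
    censored <- stats::runif(n_tum) < config$censor_rate
    time <- ifelse(censored, stats::runif(n_tum) * event_time, event_time)
    time <- pmax(time, .Machine$double.eps)
    surv <- data.frame(subject_id = c(subj_paired, subj_extra),
                       time = time, event = as.integer(!censored),
                       stringsAsFactors = FALSE)

    metadata <- data.frame(
      sample_id = c(normal_ids, tumor_ids),
      subject_id = c(subj_paired, subj_paired, subj_extra),
      condition = c(rep("normal", n_sub), rep("tumor", n_tum)),
      stringsAsFactors = FALSE)

    structure(list(expr_normal = expr_normal, expr_tumor = expr_tumor,
                   metadata = metadata, survival = surv, pairs = pairs,
                   truth = list(dc_pairs = dc, de_genes = de,
                                prognosis_pairs = pg),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic paired cohort\n")
  cat(sprintf("  genes: %d\n", nrow(x$expr_normal)))
  cat(sprintf("  normal samples: %d, tumor samples: %d\n",
              ncol(x$expr_normal), ncol(x$expr_tumor)))
  cat(sprintf("  pair list: %d pairs (%d planted DC, %d prognosis)\n",
              nrow(x$pairs), nrow(x$truth$dc_pairs),
              nrow(x$truth$prognosis_pairs)))
  cat(sprintf("  survival: %d subjects, %.0f%% censored\n",
              nrow(x$survival), 100 * mean(x$survival$event == 0)))
  invisible(x)
}

#' Write a synthetic cohort as the standard pipeline inputs
#'
#' Emits the four tab-separated inputs the pipeline reads — one expression
#' table over all samples (rows = genes, first column `gene_id`), sample
#' metadata, the gene-pair list, and the survival table — plus truth tables
#' prefixed `truth_`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  expr <- cbind(cohort$expr_normal, cohort$expr_tumor)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             survival = file.path(dir, "survival.tsv"),
             truth_dc_pairs = file.path(dir, "truth_dc_pairs.tsv"),
             truth_de_genes = file.path(dir, "truth_de_genes.tsv"),
             truth_prognosis_pairs = file.path(dir, "truth_prognosis_pairs.tsv"))
  write_expression(expr, paths["expression"])
  write_tsv(cohort$metadata, paths["metadata"])
  write_tsv(cohort$pairs, paths["pairs"])
  write_tsv(cohort$survival, paths["survival"])
  write_tsv(cohort$truth$dc_pairs, paths["truth_dc_pairs"])
  write_tsv(cohort$truth$de_genes, paths["truth_de_genes"])
  write_tsv(cohort$truth$prognosis_pairs, paths["truth_prognosis_pairs"])
  invisible(paths)
}
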