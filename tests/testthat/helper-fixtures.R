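# Small in-code fixtures shared across test files.

# random genes x samples matrix with proper dimnames
random_expr <- function(n_genes, n_samples, seed = NULL, prefix = "s") {
  draw <- function() {
    matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
           dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                           paste0(prefix, seq_len(n_samples))))
  }
  if (is.null(seed)) draw() else coexlink:::with_seed(seed, draw())
}

# standard planted-differential-coexpression configuration: 10 true pairs
# (rho 0.8 in normal, 0.0 in tumor) among 100 null pairs, 60 paired subjects
planted_dc_config <- function(seed, n_subjects = 60, rho_normal = 0.8,
                              rho_tumor = 0, n_true = 10, n_null = 100,
                              n_extra_tumor = 0, ...) {
  dc <- data.frame(gene_a = sprintf("g%04d", seq_len(n_true) * 2 - 1),
                   gene_b = sprintf("g%04d", seq_len(n_true) * 2),
                   rho_normal = rep(rho_normal, n_true),
                   rho_tumor = rep(rho_tumor, n_true),
                   stringsAsFactors = FALSE)
  sim_config(n_subjects = n_subjects, n_extra_tumor = n_extra_tumor,
             n_genes = max(2 * n_true + 2 * n_null, 2), dc_pairs = dc,
             null_pairs = n_null, seed = seed, ...)
}

# independent hand implementation of the two-group log-rank statistic:
# per distinct event time, observed minus hypergeometric-expected deaths in
# the first group, with the matching variance term
logrank_by_hand <- function(time, event, group) {
  group <- factor(group)
  g1 <- levels(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d_tot <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d_tot * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  chi <- o_minus_e^2 / v
  list(chi_square = chi, p = pchisq(chi, df = 1, lower.tail = FALSE))
}
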