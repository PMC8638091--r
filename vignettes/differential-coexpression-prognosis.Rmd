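---
title: "Differential coexpression links as prognostic markers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential coexpression links as prognostic markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexlink)
```

## The statistical model

### Product correlations

For genes $a$ and $b$ measured in $n$ samples of one condition, let
$z_{a,i}$ be gene $a$'s expression in sample $i$ after centering and
scaling to unit sample variance (denominator $n-1$). The Pearson
correlation obeys the identity

$$ r_{ab} \;=\; \frac{1}{n-1}\sum_{i=1}^{n} z_{a,i}\, z_{b,i}, $$

so the per-sample products $p_i = z_{a,i} z_{b,i}$ are sample-level
coexpression measurements. `zscore_genes()` and `product_correlation()`
implement the decomposition, and every test in the package operates on the
$p_i$ rather than on summary correlations. The identity is enforced by a
property test to $10^{-10}$ across $n \in \{5, 50, 500\}$.

Z-scoring is performed **within each condition separately** for the
differential-coexpression tests: that is what makes the per-condition sum
of products equal that condition's PCC. The survival module instead
re-scales across the tumor survival cohort only (after excluding the
normal-paired subjects), because there the products must be comparable
across patients of a single cohort. This choice is deliberate and the two
code paths are distinct (`product_correlation_records()` versus
`cohort_product_correlations()`).

### Testing coexpression change

With paired normal/tumor samples, one product value per subject and
condition, the regression of products on the group indicator degenerates
to a paired t-test on per-subject differences; `cilp_paired()` uses that
form directly. In the non-paired setting, and whenever DE-dependence
labels are wanted, `cilp_regression()` fits

$$ p_i \;=\; \beta_0 + \beta_1\,\text{group}_i + \beta_2\, z_{a,i}
   + \beta_3\, z_{b,i} + \varepsilon_i $$

by ordinary least squares and reads two-sided t-test p-values off the
coefficients. The covariates enter z-scored, not raw: the products are
themselves defined on z-scores, and scale-free covariates keep the
coefficients comparable across pairs.

Group p-values are adjusted with Benjamini–Hochberg over the family of
all pairs tested in a run; links at FDR $\le$ 0.3 are accredited as
differentially coexpressed links (DCLs) in the permissive pan-cancer-style
screen, with 0.1 used for the stricter reproducibility analysis. Both
cutoffs are arguments, not constants.

The two covariate p-value columns are pooled into a **single** BH family
per run, and a link is DE-dependent when the smaller of its two adjusted
covariate values falls below 0.1. Pooling matches the "at least one gene
entity" reading with one correction; correcting each covariate column
separately would be defensible too, but would make the label depend on an
arbitrary assignment of genes to columns.

### Survival screening

Per DCL, the cohort product values are split at the across-cohort median:
strictly above the median is high-coexpression, at or below is low. Ties
go to low — deterministic and reproducible; with continuous expression
ties have probability zero anyway. The two groups are compared with the
standard two-group log-rank test (observed minus hypergeometric-expected
deaths summed over distinct event times, chi-square with 1 df), computed
by `survival::survdiff()` and verified in the test suite against a
hand-summed per-event-time oracle. Log-rank p-values are BH-adjusted over
all DCLs screened in the run, and FDR $\le$ 0.3 flags prognosis DCLs. The
`worse_group` annotation records which coexpression group has more
observed than expected deaths. Only overall survival with right censoring
is modeled; multivariate (Cox) covariate adjustment is out of scope by
design.

### Landscape, reproducibility, enrichment

A pair is *Strengthened* when $|r_{\text{tumor}}| > |r_{\text{normal}}|$,
strictly; the tie is counted as Weakened, the conservative direction for
any claim of tumor coexpression attenuation. Sign patterns compare the
signs of the two correlations, with an exact zero treated as positive (a
measure-zero event for continuous data). The attenuation summary is the
OLS slope of tumor PCC on normal PCC — attenuation by a factor $a$
appears as slope $\approx a$, and the test suite checks recovery of
$a = 0.5$ within [0.4, 0.6].

Half-thresholding keeps the union of the top $\lceil q M \rceil$ pairs by
absolute PCC in either condition ($M = n(n-1)/2$ candidate pairs,
$q = 0.01$ by default). Ceiling plus all boundary ties means the selected
count can slightly exceed $\lceil q M \rceil$; admitting ties avoids an
order-dependent cut.

Reproducibility analysis follows the cohort-splitting design:
`split_folds()` either balances fold sizes to within one sample or, given
a `target_size`, fills $k-1$ folds exactly and leaves the remainder in the
last fold (1093 samples at nine folds of 112 leave 85). Reference DCLs
come from one paired run at FDR < 0.1; the repeated runs use the
regression test of each tumor fold against the fixed normal set, and
recurrence (0..k) is tallied per reference link, stratified by
DE-dependence and sign pattern.

The enrichment module asks whether DCL genes (DCGs) sit unusually high or
low in a DE ranking. The ranking score is
$\operatorname{sign}(\bar{x}_T - \bar{x}_N)\cdot(-\log_{10} p)$ from a
plain paired t-test — a deliberately self-contained ranking; moderated
(empirical-Bayes) DE statistics are not used because only the ordering is
consumed downstream. The enrichment score is the standard weighted
Kolmogorov–Smirnov running-sum statistic (weight 1 by default; weight 0
reduces to the classic KS statistic, which the tests exploit as an
oracle). Significance is two-sided on $|ES|$ by gene-label permutation,
$p = (1 + \#\{|ES^*| \ge |ES|\})/(B+1)$, because DCGs could plausibly
concentrate at either extreme. On a 20-gene instance the permutation
p-value is checked against exhaustive enumeration of all 15,504
same-size sets.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not RNA-Seq data per se:

* Background genes are independent Gaussians on the log2 scale (mean 8,
  SD 1 by default) — the simplest model satisfying the analysis
  assumptions after log transformation and quantile normalization.
* Planted DC pairs are bivariate normal with condition-specific
  correlations (`rho_normal`, `rho_tumor`), sampled by the Cholesky
  construction; planted DE genes receive an additive log2 fold change in
  tumor.
* Survival is exponential: a tumor subject's log hazard is
  $\log(\lambda_0) + \sum_j \log(HR_j)\,\mathbb{1}[p_{j} > \text{median}]$
  over the prognosis pairs $j$ — a dichotomized-covariate model chosen to
  mirror the median-split log-rank screen, rather than a continuous
  proportional-hazards model. Censoring is independent with probability
  `censor_rate` (default 0.3, typical moderate follow-up), realized as a
  uniform draw before the event time.
* One integer seed drives a single private generator (`with_seed`), so
  identical configurations reproduce byte-identical cohorts without
  disturbing the caller's RNG state.

What the generator does **not** emulate: negative-binomial count noise,
library-size variation, batch effects, and correlated background
structure. Consequently, passing tests demonstrate correctness of the
statistical machinery under its own assumptions — calibration, planted
recovery, identities — not robustness to RNA-Seq artifacts; on real data
the preprocessing steps (log transform, within-group quantile
normalization) carry that burden.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `dcl_fdr` | 0.3 | BH cutoff accrediting DCLs (permissive screen) |
| `survival_fdr` | 0.3 | BH cutoff for prognosis DCLs |
| `de_dependence_fdr` | 0.1 | pooled covariate-FDR cutoff for DE-dependence |
| `half_threshold_fraction` | 0.01 | top fraction kept per condition |
| `min_matched_pairs` | 20 | minimum paired subjects; smaller cohorts refused |
| `pseudocount` | 1 | offset in `log2(x + c)`; zero counts map to zero |
| `baseline_hazard` | 0.002 /time unit | exponential rate, low-coexpression group |
| `censor_rate` | 0.3 | independent censoring probability |

The log base (2) and pseudocount (1) are conventions; any positive base
changes correlations not at all and t statistics only through a global
scale.

## Numerical choices and degenerate inputs

* Zero-variance genes cannot be z-scored; they are excluded and reported
  (`rejects` attributes), never silently dropped.
* A zero-variance, nonzero product difference makes the paired t statistic
  infinite; the p-value is set to the smallest positive double and flagged
  `degenerate` rather than dropping the pair — it is, after all, maximal
  evidence of change.
* Rank-deficient regression designs raise an error naming the pair rather
  than returning aliased coefficients.
* Quantile normalization resolves within-column ties by averaging the tied
  target quantiles (`limma::normalizeQuantiles(ties = TRUE)`); with no
  ties the operation is idempotent and equalizes column means to
  $10^{-12}$.
* With zero observed events the log-rank p is reported as 1 and flagged;
  an all-constant product vector yields an all-low split, flagged
  degenerate.

## Problem sizes in the test suite

The suite exercises the pipeline at desk scale: cohorts of 20–60 paired
subjects with up to 200 extra tumor samples and 100–2000 gene pairs;
calibration checks use 1000 null pairs and 1000 log-rank replicates;
planted-recovery checks use 20 replicates of 10 true among 100 null pairs
(coexpression) and of one hazard-ratio-3 link among 50 null links
(survival). These sizes give the binomial/KS checks their stated
resolution (e.g. 3 binomial SDs of 0.05 at 1000 replicates is about
±0.021) while keeping a full run in tens of seconds.

## Known limitations

* Two conditions only; no multi-group or continuous-phenotype CILP.
* Gaussian-oriented: Pearson correlation and OLS inherit sensitivity to
  heavy tails and outliers; the quantile normalization mitigates but does
  not remove this.
* The survival screen is univariate; confounders (age, stage, subtype)
  are not adjusted for.
* The enrichment module handles one gene set per call — no collection-wide
  normalized enrichment scores or FDR across sets.
* The generator's independence assumptions make false-positive control
  easier than in real transcriptomes, where correlated backgrounds inflate
  the effective number of dependent tests.
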