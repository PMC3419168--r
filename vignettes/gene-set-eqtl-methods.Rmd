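---
title: "Gene-set eQTL mapping: model, calibration and design notes"
author: "GSeQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set eQTL mapping: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GSeQTL)
```

# The model

Classical eQTL mapping regresses every expression trait on every SNP, an
enormous multiple-testing burden with weak power for coordinated but
individually modest effects. GSeQTL instead asks a pathway-level
question: is the joint genetic variation of one gene set associated with
the joint expression variation of a gene set?

For each set, the member genes collect their SNPs (any SNP within a
flanking window of the gene body, 20 kb by default, both boundaries
inclusive) and their expression probe sets (through a platform
probe-to-gene map). Both collections are deliberately multimaps: a SNP in
the overlap of two flanks, a probe interrogating two genes, and a gene in
several pathways all contribute everywhere they belong.

Each side of a set pair is reduced by principal component analysis of the
covariate-adjusted values, retaining the smallest number of components
whose cumulative variance fraction reaches `varThreshold` (default 0.80; a
component landing exactly on the threshold terminates the count). With
$X$ ($n \times p$) the SNP scores and $Y$ ($n \times q$) the expression
scores, the model is the multivariate linear regression

$$Y = B_0 + B_1 X + E, \qquad E \sim N(0, \sigma^2),$$

and the association test is of $H_0: B_1 = 0$ with Wilks' lambda,
$\Lambda = \det(E)/\det(E + H)$, where $E$ is the residual SSCP and $H$
the SSCP of fitted values about the grand mean. P-values come from Rao's
F approximation, which is exact when $\min(p, q) \le 2$ and reduces to
the univariate overall-regression F test when $q = 1$ — both facts are
exploited as independent oracles in the test suite (the suite checks the
implementation against `stats::anova.mlm`, which it shares no code with).

A pair is labeled *cis* when the SNP set and the expression set are the
same named set, *trans* otherwise; all $G^2$ ordered pairs over the $G$
testable sets are tested.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `call_rate` | 0.95 | samples and SNPs below this observed fraction are removed (strict `<`) |
| `maf_min` | 0.05 | minimum minor allele frequency (strict `<` removes) |
| `hwe_alpha` | 0.001 | Hardy–Weinberg chi-square p below this removes the SNP |
| `winsor_k` | 4 | expression clamped at mean ± k·SD (single pass) |
| `flank_bp` | 20000 | SNP-to-gene window, inclusive at both ends |
| `var_threshold` | 0.80 | cumulative variance fraction retained by PCA |
| `n_permutations` | 10000 | permutation replicates behind the empirical FDR |
| `fdr_cut` | 0.05 | significance cutoff used in reports |
| `n_strat_pcs` | 2 | stratification eigenvectors added to the covariates |

The defaults are the method's standard operating point; every one is a
named config key so deviations are visible in the config echo written
next to the results. The number of stratification eigenvectors is
genuinely a free choice (two captures a two-population structure; panels
mixing k ancestral groups warrant k − 1 or more, guided by the eigenvalue
spectrum).

# Preprocessing order and its consequences

The pipeline applies, in order: sample call-rate filter, SNP filters
(call rate, then MAF, then HWE, each recomputed on observed genotypes
after sample removal), additive encoding with mean-dosage imputation,
expression winsorization, and residualization of **both** dosages and
expression on an intercept plus covariates (indicator-expanded factors,
then stratification eigenvectors). Winsorization is applied before
covariate adjustment, matching the natural reading of the preprocessing
recipe; clamping after adjustment is a defensible alternative that
changes little when outliers are rare. Winsorization is a single-pass
rule — mean and SD are computed once, outliers included — and is
therefore not an exact fixed point when an extreme outlier materially
inflates the SD; it is not iterated.

HWE uses the 1-df chi-square goodness-of-fit test without continuity
correction (the standard choice for the era of the thresholds above);
monomorphic triples return p = 1 by convention and are removed by the
MAF rule instead.

# Degrees of freedom after covariate adjustment

Residualizing both sides on $c$ covariate columns confines the observed
$X$ and $Y$ to the same $(n - 1 - c)$-dimensional subspace. Testing with
the nominal sample size then overstates the error degrees of freedom and
inflates type-I error noticeably (we measured 0.12 at nominal 0.05 with
$c = 4$, $n = 60$). Observed tests therefore use an effective sample size
$n - c$. Permutation replicates are the opposite case: a row-permuted
expression block sits in generic position relative to the
covariate-orthogonal subspace — exactly as in a from-scratch re-analysis
of shuffled adjusted data — so replicate p-values use the full $n$. With
both choices, observed and replicate p-values are uniform under a global
null (the acceptance suite verifies empirical $\alpha$ within binomial
99% bounds of 0.05 and Kolmogorov–Smirnov uniformity across 500+ null
tests).

# Component cap

Rao's approximation needs error degrees of freedom at least the response
count, $n_\mathrm{eff} - p - 1 \ge q$; nothing in the 80% rule guarantees
it (a large set can retain more components than samples allow). When the
inequality fails, SNP components are dropped from the smallest-variance
end first, then expression components, until the test is well posed; the
cap is recorded per pair (`capped` column) and logged. This keeps $E$
nonsingular deterministically instead of failing on large sets.

# Permutation FDR

Replicates shuffle the expression sample labels while holding genotypes
fixed; one shared permutation per replicate is applied to every set so
the between-test correlation is preserved in the null. Because a row
permutation of a matrix permutes its centered-PCA scores identically,
the per-set expression scores are permuted directly instead of re-running
the PCA — a pure optimization, verified against full recomputation to
1e-12 in the suite. All `B` permutations are drawn up front from the run
seed with R's default generator, making the null reproducible and
chunk-safe (a per-replicate counter substream would serve equally; the
up-front draw is simpler to audit).

The estimator pools across tests:
$$\widehat{\mathrm{FDR}}(p) = \frac{\tfrac1B \sum_b \#\{p^{(b)} \le p\}}
{\#\{p^{obs} \le p\}},$$
clipped to $[0, 1]$ and made monotone non-decreasing in $p$ by a
cumulative minimum from the largest p downward. Pooling over the
$B \times T$ null draws gives the estimator a resolution of about
$1/(BT)$, so FDR values far below $1/B$ are attainable at scale.

Pairs untestable in the observed analysis (no SNPs, no probes, no
variance) are excluded from every replicate, keeping numerator and
denominator on the same test set.

# The cis-versus-trans question

Whether significant findings are disproportionately cis is tested two
ways: a two-sided Fisher exact test on the 2×2 (cis/trans ×
significant/not) table, and a permutation variant that recomputes the
cis-minus-trans significant-proportion difference on every replicate and
compares the observed difference against that null. The Fisher test is
the default; the permutation variant reuses the existing null at no extra
simulation cost. An empty table margin returns p = 1 with a warning.

# The synthetic-data generator

`scenarioSpec()` fixes the study conditions: 60 samples, 6 disjoint sets
of 5 genes, 3 SNPs and 2 probes per gene, MAF uniform on [0.1, 0.4],
batch and sex effects of 0.5 on the log2 scale, unit residual noise, and
per-gene baselines N(8, 1) — sizes and magnitudes typical of a small cell
line expression panel. Genotypes are drawn in Hardy–Weinberg equilibrium;
two-population structure follows the Balding–Nichols model (per-SNP
population frequencies Beta-distributed around the ancestral MAF with
parameter `fst`), the simplest standard generator that makes
stratification adjustment testable. Gene loci are non-overlapping with
100 kb spacing so 20 kb flanks never collide; sets are sliding windows
over the gene list with configurable overlap, exercising the
$1 - \tau$ distance. Planted effects add $\beta \times$ dosage of each
causal SNP (drawn from the source set) to every probe of the target set —
exactly the linear-additive class the test assumes, which is what makes
the power and type-I claims interpretable.

What the generator does **not** emulate: linkage disequilibrium from
recombination maps (SNPs are independent given ancestry), heavy-tailed
microarray noise, probe cross-hybridization, and expression correlation
beyond what shared genotype and covariates induce. Passing tests
demonstrate correctness of the machinery under the model's own
assumptions, not robustness to violations of them.

# Numerical choices

* PCA is SVD-based on centered (not rescaled) values — both inputs are
  residuals on comparable scales; a `scale.` switch enables
  correlation-based PCA. Components with singular values at machine-zero
  are dropped. Component signs are fixed by making the largest-magnitude
  loading positive, so results are deterministic across platforms and
  invariant to column reordering.
* The cumulative-variance comparison uses a 1e-9 slack so a component
  landing exactly on the threshold terminates despite floating-point
  round-off.
* $\Lambda$ is computed from log-determinants (Cholesky-backed
  `determinant()`); a numerically singular $E$ maps to the smallest
  positive double rather than a negative or zero value.
* Minor-allele orientation flips a column only when the counted-allele
  frequency strictly exceeds 0.5; a tie keeps the alt allele — a
  deterministic, VCF-anchored convention.
* Set clustering uses complete-linkage `hclust`; with all distances tied
  the input order is preserved.
* The $1-\tau$ distance averages the two directed overlap proportions;
  it is symmetric and zero only for equal sets, but not a metric (the
  triangle inequality can fail), so it is used only for ordering and
  reporting.

# Problem sizes in the test suite

The suite exercises the pair-count laws at 60 and 201 sets (3,540 and
40,200 trans tests), calibration on 504 aggregated null tests (14 seeds),
power on 100 seeds of a planted cis effect ($\beta = 1$, noise SD 1,
n = 100), and null-FDR behavior over 20 seeds at B = 200 — sizes chosen
so the whole suite completes in a couple of minutes while leaving the
statistical claims well-resolved.

# Known limitations

* An empirical FDR threshold controls the expected false fraction among
  discoveries, not the probability of any false discovery: under a
  global null, roughly an $\alpha$ fraction of datasets still yield at
  least one finding at FDR < $\alpha$. That is inherent to FDR, not an
  artifact.
* Rao's F is approximate when $\min(p, q) > 2$; at the sample sizes and
  component counts used here the approximation error is far below the
  permutation resolution.
* PCA captures linear structure only; strongly nonlinear
  genotype-expression relationships dilute across components.
* Mean-dosage imputation is adequate for the low missingness the QC
  admits (< 5%); reference-panel imputation is out of scope.
* Gene-level attribution is deliberately absent: a significant set pair
  is a hypothesis generator, and the `pairwiseEqtl()` follow-up (simple
  per-pair regressions with Bonferroni adjustment within the pair) is
  provided to localize drivers afterwards.
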