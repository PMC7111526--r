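---
title: "Methods: metabolome quantitative genetics on an inbred-line panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome quantitative genetics on an inbred-line panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods, the synthetic-panel
generator, the numerical choices, and the limitations of `metaboqg`. All code
chunks are illustrative (`eval = FALSE`); the package's behavior is pinned by
its test suite, not by this document.

## Study design and assumptions

The package targets a DGRP-style design: a panel of fully inbred,
unrelated lines, each measured in both sexes with a small number of
replicates per line–sex cell. Inbreeding has two consequences used
throughout:

* Genotypes are effectively biallelic and homozygous, coded 0/1 per line.
  Heterozygous calls in input VCFs are treated as missing (with a logged
  count) rather than dosage-coded.
* A line's replicate average ("line mean") estimates its genotypic value, so
  line means are the unit for correlation, mapping, and prediction, while
  replicate-level data feed the variance-component models.

Because the lines are assumed unrelated and free of the usual panel
covariates (inversions, endosymbionts), association mapping reduces to
two-class OLS per variant — a deliberate simplification that is exact for the
synthetic panels and the faithful reduction of the standard panel pipeline.

## Variance components and heritability

Per metabolite, with sexes pooled:

$$Y = \mu + L + S + L{\times}S + \varepsilon,$$

with line $L$ and interaction $L{\times}S$ random, sex $S$ fixed; within one
sex the model reduces to $Y = \mu + L + \varepsilon$. Fits use REML
(`lme4::lmer`). For the balanced case the package also implements the
method-of-moments (EMS) estimators:

$$\hat\sigma^2_e = MS_E,\quad
  \hat\sigma^2_{L\times S} = (MS_{L\times S} - MS_E)/r,\quad
  \hat\sigma^2_{L} = (MS_L - MS_{L\times S})/(sr),$$

truncated at zero. When all components are interior, REML and EMS agree to
optimizer precision; the tests exploit this as an independent oracle.
Broad-sense heritability is
$H^2 = (\sigma^2_L + \sigma^2_{L\times S})/(\sigma^2_L + \sigma^2_{L\times S} + \sigma^2_e)$.

Significance of the random terms uses REML likelihood-ratio tests against the
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ boundary mixture. The mixture P-value
is only asymptotically calibrated; the EMS F-tests (exactly uniform under the
balanced normal null) are exposed as `method = "ems"` and used for the
calibration tests. Line-term P-values are BH-adjusted across metabolites and
a metabolite is flagged "genetically variable" at FDR 0.05.

## Modules and module PCs

Absolute Pearson correlations of line means are soft-thresholded with a
sigmoid $w = 1/(1+\exp(-s(|r|-t)))$, evaluated over the small grid
$s \in \{5, 10, 20\}$, $t \in \{0.3, 0.5, 0.7\}$; the partition with the
highest modularity across the grid wins. Clustering is
modularity-maximizing agglomeration (`igraph::cluster_fast_greedy`), with
the maximum-modularity cut selected explicitly from the merge tree (ties
resolved toward fewer modules) because the library's own cut can return a
non-maximal split on degenerate weight configurations. Edges exist only for
$|r| > 0$, so an identity correlation matrix yields singletons. Modules are
numbered by decreasing mean within-module $|r|$.

Module PCA standardizes each analyte (modules mix measurement scales), then
retains every PC explaining more than 4% of the module's variance, extending
the retained prefix until cumulative variance exceeds 90%. Note the rule's
two-sided character: a second PC at 5% is retained even when PC1 alone
explains 95%. PC signs are fixed so the largest-magnitude loading is
positive.

## mQTL mapping

Variants pass when the minor genotype class covers at least
`min_minor_lines = 4` lines (MAF ≥ 0.1 at 40 lines). Each phenotype (line
means, module PC scores) is regressed on each variant; the two-sided t
P-value from the pooled-variance two-sample statistic is identical to the
OLS slope test, and the scan is vectorized across variants. The genome-wide
threshold is Bonferroni, $\alpha / (\text{variants} \times \text{phenotypes})$.
Hits are annotated with containing genes (1-based, closed spans); intergenic
hits are merged by single linkage whenever consecutive positions on a
chromosome are ≤ 2000 bp apart. A relaxed, top-N-by-P selection is provided
for phenotypes (such as module PCs) with no genome-wide hits.

## MWAS, trait clustering, networks

Trait screens use Spearman rank correlation over pairwise-complete lines, at
least 5 pairs per test. For n ≤ 8 complete pairs the two-sided P-value is
computed by exact enumeration of all permutations; otherwise by the
t-approximation. Traits are clustered on their signed correlation profiles
(non-significant entries zeroed), distance $1 - \text{Pearson}$, average
linkage, exported as Newick.

Networks per trait and sex: metabolites at nominal P < 0.05 with the trait;
transcript links at $|\rho| > 0.45$; each linked metabolite's mQTLs re-tested
against the linked transcripts and kept at $0.05 / (\text{that metabolite's
mQTL count})$ — the metabolite-specific Bonferroni rule taken literally.
meQTLs are cis when the variant lies within the gene body ± 1 kb on the same
chromosome. Nodes are typed (metabolite / gene / variant), edges typed and
signed, isolated nodes dropped, output GraphML.

## Prediction

Kernels are $K = WW'/p$ with columns centered and scaled by the sample SD
($n-1$ denominator), so $\mathrm{tr}(K) = n-1$. One- and two-kernel BLUP
models $y = 1\mu + g_{K_1} (+ g_{K_2}) + e$ are fit by bounded REML
(Cholesky-based criterion, L-BFGS-B from three starts). With a fixed variance
ratio, the kernel BLUP equals ridge regression on $W$ with penalty
$p\,\sigma^2_e/\sigma^2_K$; the tests verify this to 1e-8.

Leave-one-out CV re-centers and re-scales features on the training lines
only, rebuilds the kernel, and re-estimates variance components per fold.
The combined MWAS-BLUP runs single-metabolite regressions inside each
training fold and selects metabolites at P < x, x ∈ {0.5, …, 0.05}; folds
with an empty selection fall back to the training mean (logged). The elastic
net searches α ∈ (0, 1] on a shared 50-value λ path spanning four decades
below the full-data λ_max; the reported model is the grid point with the
best LOOCV accuracy (non-nested, matching common practice), with a nested
inner-LOOCV mode available as the conservative alternative.

A statistical caveat documented here because it shapes the tests: under the
null (no signal), per-fold LOOCV BLUP accuracy is *negatively* biased. When
REML estimates zero genetic variance, the fold predicts its training mean,
and $\mathrm{cor}(\bar y_{-i},\, y_i) = -1$ for any $n$. Permutation nulls
therefore bound accuracy from above (no positive leakage) rather than
asserting a symmetric band around zero.

## The synthetic generator

`sim_config()` / `simulate_panel()` generate, in order (each sub-generator
offsets the seed deterministically, so components are individually
reproducible): genotypes with a minor-class floor; a metabolome with planted
line variance calibrated to a target H² (default 0.43, split 80/20 between
line and line-by-sex), planted correlation modules (factor structure of
strength ρ), planted mQTL effects in residual-SD units, and a fixed sex
offset; per-sex transcripts with planted eQTLs; organismal traits as linear
combinations of metabolite line means plus noise scaled to a target trait
h²; a non-overlapping gene model; and super-pathway annotations enriched
within modules.

What it emulates: normalized abundances on a replicable inbred panel with
known genetic architecture. What it does not: measurement-platform artifacts
(batch/run-day effects, censoring at detection limits), linkage
disequilibrium between variants (genotypes are independent), population
structure, or dominance (impossible in fully inbred lines).

Default sizes (40 lines, 200 metabolites, 3 replicates, 5,000 variants in
the analysis scripts) are the package's own desk-scale choices: large enough
that H² recovery, null calibration, and power properties are testable in
minutes, small enough to run anywhere.

## Numerical choices

* REML for kernel BLUP uses the Cholesky-based criterion
  $\log|V| + \log|X'V^{-1}X| + r'V^{-1}r$; failures return a large penalty
  so bounded optimization stays inside the feasible region.
* PSD tolerance for kernels: smallest eigenvalue ≥ −1e-8 · trace/n.
* Exact Spearman permutation P uses a 1e-12 slack when comparing |ρ| values
  to absorb floating-point ties.
* All file writes are atomic (temp + rename); pipeline outputs are
  checksummed (md5) into `manifest.json`, and reruns with the same config
  and seed are byte-identical.

## Limitations

* Association mapping ignores relatedness and covariates by design; it is
  not suitable for structured panels.
* The boundary-mixture LRT is asymptotic; at very small line counts use the
  EMS F-tests.
* Elastic-net non-nested grid selection optimizes the reported accuracy and
  is optimistically biased; use `nested = TRUE` for honest model selection.
* The generator's independence assumptions (no LD) make mQTL localization
  trivial compared to real data; positional annotation logic is exercised,
  but fine-mapping behavior is not.
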