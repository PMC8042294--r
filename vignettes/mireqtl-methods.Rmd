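---
title: "Methods: weighted GBLUP mapping of miRNA expression QTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted GBLUP mapping of miRNA expression QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model the package implements, the
choices made where the design was genuinely open, the synthetic-data
generator that serves as its test bed, and the numerical details a
maintainer would want written down.

## The expression model

Each miRNA's normalized expression across `n` individuals is modelled as

$$ y = X\beta + a + e, \qquad
   a \sim N(0,\, G\sigma_a^2), \qquad
   e \sim N(0,\, \sigma_e^2\,\mathrm{diag}(1/\hat w)), $$

with $G = ZZ'$ the genomic relationship matrix built from standardized SNP
dosages (each marker column centered, scaled to unit observed variance, and
divided by $\sqrt{m}$ so the average diagonal of $G$ is about 1), $X$ the
fixed-effect design (intercept, sex, four-level growth group by default),
and $\hat w$ the per-observation voom precision weights. Narrow-sense
heritability is the variance share $h^2 = \sigma_a^2/(\sigma_a^2 +
\sigma_e^2)$.

Assumptions worth stating: additive SNP effects only (no dominance or
epistatic kinships), a single shared $G$ for all miRNAs, Gaussian residuals
on the log2-CPM scale after precision weighting, and fixed effects known and
low-dimensional relative to $n$.

### Marker standardization

Columns of $Z$ are scaled by the observed genotype standard deviation
(default), which makes every marker contribute equal variance to $G$
regardless of allele frequency. The population-genetics alternative,
$\sqrt{2p(1-p)}$ scaling, is available via `build_grm(scale = "2pq")`; the
two differ only when genotypes depart from Hardy–Weinberg variance, as they
do in structured crosses.

## Normalization

Counts are filtered *before* normalization factors are computed: a miRNA is
removed iff its CPM — computed on raw library sizes, since TMM factors do
not exist yet — falls below `cpm_threshold` (default 1) in at least
`min_fail_libraries` (default 44, the conventional rule for a ~174-library
panel; scale it with your sample size). TMM factors and the voom transform
are delegated to `edgeR::calcNormFactors(method = "TMM")` and
`limma::voom`, the canonical implementations of those published procedures;
the package adds the contract around them: log2-CPM by the closed form
$\log_2\!\big((c + 0.5)/(L f + 1) \times 10^6\big)$, a positive floor
(1e-6) under the weights, and a refusal to fit the mean–variance trend with
fewer than 10 miRNAs (weights are then 1, with a warning). The voom design
matrix defaults to the same fixed effects used downstream (sex + growth
group); the trend is not meaningfully sensitive to this choice but the
default keeps the residual standard deviations consistent with the model
actually fit.

## REML, heritability testing

The restricted likelihood is profiled over the variance ratio
$\lambda = \sigma_a^2/\sigma_e^2$: with $S = \mathrm{diag}(\sqrt{\hat w})$,
the eigendecomposition $S G S = U D U'$ rotates the model so the covariance
is $\sigma_e^2(\lambda D + I)$, and for fixed $\lambda$ both $\beta$ and
$\sigma_e^2$ have closed-form REML solutions. A Brent search on
$\log\lambda \in [-10, 10]$ (tolerance 1e-8) then maximizes a 1-D function;
the bounds correspond to $h^2$ between $\sim 5\times10^{-5}$ and
$1 - 5\times10^{-5}$ and the boundary $\lambda = 0$ is always evaluated
explicitly, so $\hat\sigma_a^2 = 0$ is attainable exactly. This profile
approach is derivative-free, cannot step outside the parameter space, and
costs one $n \times n$ eigendecomposition per miRNA — cheap enough to refit
thousands of times in the conditional stages.

Two reporting conventions matter:

* **Weight scale.** Precision weights are only defined up to a constant, but
  $h^2$ is a ratio of components, so the component labelled $\sigma_e^2$
  must mean "average residual variance". Weights are therefore rescaled
  inside the fit so that $\mathrm{mean}(1/w) = 1$. The fitted covariance,
  $\beta$, the LRT and all association statistics are invariant to this;
  only the split of $(\sigma_a^2, \sigma_e^2)$ into interpretable units
  depends on it.
* **LRT reference.** Testing $h^2 = 0$ places the parameter on the boundary,
  so the LRT is referred to the 50:50 mixture of a point mass at zero and
  $\chi^2_1$: $p = \tfrac12 P(\chi^2_1 > \mathrm{LRT})$, and $p = 1$ when
  LRT $= 0$. A plain $\chi^2_1$ reference (conservative) is available via
  `null_dist = "chisq1"`.

FDR control across miRNAs is Benjamini–Hochberg by default; a Storey-type
q-value (single-$\lambda$ $\pi_0$ estimate at 0.5) is available with
`method = "storey"`. BH is the default because it is assumption-light and
reproducible without tuning; with hundreds rather than tens of thousands of
tests the difference is small.

## GWA by backsolving

Per-SNP effects are a linear transformation of the predicted breeding
values, $\hat g = Z'G^{-1}\hat a$ with
$\mathrm{var}(\hat g) = \mathrm{diag}(Z'G^{-1}\mathrm{var}(\hat a)G^{-1}Z)$
and $t_j = \hat g_j/\sqrt{\mathrm{var}(\hat g_j)}$. Because $\hat a =
\sigma_a^2 G P y$ lies in the range of $G = ZZ'$, these expressions reduce
to $\sigma_a^2 Z'Py$ and $\sigma_a^4\,\mathrm{diag}(Z'PZ)$ for *any*
generalized inverse of $G$ — so the implementation never inverts $G$, and
rank deficiency costs nothing. The same algebra shows $t_j$ equals the GLS
t-statistic of SNP $j$ fitted as a fixed effect with the covariance frozen
at the no-SNP REML fit; the test suite asserts this equivalence against an
explicit per-SNP GLS oracle at relative error 1e-6, including with
non-uniform weights.

$t$ is referred to the standard normal (two-sided) by default;
`p_reference = "t"` switches to a $t$ distribution with $n -
\mathrm{rank}(X) - 1$ df. The multiple-testing universe is all
(miRNA, SNP) tests jointly — matching the convention in which "N significant
miRNA–SNP associations" is a single tally — with a per-miRNA mode behind
`universe = "per_mirna"`.

### Peaks and local/distant classification

Significant SNPs of one miRNA are grouped per chromosome; adjacent
significant SNPs within `merge_gap_bp` (default 20 Mb) join one peak. The
default gap is a compromise: wide enough to absorb LD-scale gaps inside one
signal in a low-recombination cross, narrow enough to keep signals tens of
megabases apart as separate peaks. It is a parameter, not an inference. The
peak SNP is the member with minimum p (ties to the smaller position), and a
peak is a *local* regulator iff its range — a point for single-SNP peaks —
overlaps the precursor interval on the same chromosome under closed-interval
arithmetic; precursors on unplaced scaffolds yield `unplaced`.

## Conditional analysis

`conditional_fit()` augments $X$ with the fixed SNP's dosage as one numeric
covariate (1 df), because the variance-explained formula
$\widehat{\mathrm{Var}}(q) = b^2\,\mathrm{var}(z_{\text{peak}})$ uses a
single scalar effect; a 3-level factor encoding is available
(`encoding = "factor"`), in which case $b$ is undefined and
$\widehat{\mathrm{Var}}(q)$ is the sample variance of the genotype-class
fitted values. The dosage variance uses the $n-1$ denominator. The
proportion of variance explained,
$\widehat{\mathrm{Var}}(q) / (\hat\sigma_a^2 + \hat\sigma_e^2 +
\widehat{\mathrm{Var}}(q))$, uses the *conditional* fit's components by
default (they appear alongside $\widehat{\mathrm{Var}}(q)$ in the formula);
the unconditional alternative is exposed. On re-backsolving, the fixed SNP
is excluded from the test set and $G$ is *not* rebuilt — the single-$G$
workflow — with rebuilding available in principle by refitting a reduced
`build_grm`.

Outcomes: `explained_by_snp` (nothing stays significant),
`cross_genome_correlation` (the only lost peaks sit on a different
chromosome than the fixed SNP while other signal remains),
`independent_loci` (peaks remain), and `collinear_failure` when the SNP is
monomorphic or collinear with the design — recorded, not raised, since in
strong-LD populations this failure is an expected result, not a bug.

## Colocalization and correlation layers

eQTL–pQTL colocalization is closed-interval overlap of peak ranges with
five types (identical, either containment, partial up/downstream); any
nonzero intersection counts, with no minimum-width requirement. "Corrected"
expression removes both the fitted fixed effects and the predicted breeding
values ($y - X\hat\beta - \hat a$); fixed-only correction is a flag.
miRNA–target association uses Kendall's tau-b (tie-corrected — count-derived
residuals rarely tie, phenotype ranks may), with exact permutation
enumeration of the p-value for $n \le 8$ and the tie-corrected normal
approximation otherwise, BH across all pairs, and retention of negative
significant pairs — the assumed repressive direction. Gene/miRNA–phenotype
layers use Pearson's r with the $t_{n-2}$ reference; a target is reported
"of interest" when retained *and* either its own or its miRNA's phenotype
correlation reaches p < 0.05.

## The synthetic-data generator

The generator emulates the statistical structure the model assumes, at the
scale of an F2 livestock resource population:

* **Genotypes.** 174 samples and 2,000 markers by default (a thinned stand-in
  for a medium-density chip), in LD blocks of 50 markers sharing a
  per-gamete latent factor with loading $\sqrt{0.9}$; thresholding the
  latent Gaussians at frequency-specific cutoffs gives dosages in {0,1,2}
  with strong within-block and zero between-block correlation. Markers whose
  empirical MAF leaves the configured window (default [0.10, 0.50],
  mirroring a MAF < 0.10 exclusion) are redrawn keeping their block factor,
  so the filter does not erode LD. Block size is a free parameter — the LD
  decay of any particular population is not being inferred.
* **Counts.** Latent log2-expression = baseline (uniform 4–10 log2-CPM) +
  sex and growth-group effects (sd 0.5) + planted causal-SNP effects +
  polygenic term (Cholesky factor of $G$ with ridge 1e-8) + Gaussian
  environment; counts are negative binomial with dispersion 0.1 (so the
  voom weights have real heteroskedasticity to model) and library sizes
  uniform in [0.8M, 1.2M]. The planted $h^2$ refers to the *observed*
  log-expression: the count layer adds (delta-method) variance
  $\approx (\log_2 e)^2(\phi + 1/\mu)$, and the polygenic variance is
  inflated to keep $\sigma_a^2/(\sigma_{\text{latent}}^2 + v_{\text{count}})$
  at the target. Heritabilities that would require negative environmental
  variance under this budget are refused at generation time.
* **Phenotypes, genes, targets.** Phenotypes are planted pQTL dosage effects
  plus a sex effect and unit-variance noise. Target genes follow
  `baseline + coupling × (miRNA latent) + noise` with coupling ≤ 0 — the
  repressive direction; with default latent scale, couplings around −0.25
  put retained tau-b values in the weak negative band characteristic of
  miRNA–target correlations in tissue data.

What the generator does **not** emulate: family pedigree structure,
LD decay within blocks, sequencing-depth batch effects, zero inflation,
isomiR composition, or any read-level process. Tests passing on this bed
show the estimators recover the model's own quantities under the model's
assumptions — not that those assumptions hold for any particular real
dataset.

## Validation conditions

The statistical validation suite runs at fixed problem sizes chosen to make
Monte Carlo error small relative to the tolerances while staying desk-scale:
20 datasets of $100 \times 500$ for the backsolve/GLS identity; 200 miRNAs
per $h^2 \in \{0, 0.2, 0.4, 0.6\}$ at $n = 200$ (tolerance 0.05 on the mean);
1,000 null miRNAs at $n = 174$ for LRT calibration (rejection in
[0.035, 0.065] at $\alpha = 0.05$); 200 global-null replicates for peak-level
error control; and 100 replicates each for localization (planted variance
share 0.3 at $n = 174$) and conditional recovery.

## Numerical choices and degenerate inputs

* Eigenvalues of the weighted $G$ are clipped at zero; the ridge for the
  generator's Cholesky is 1e-8 × mean diagonal.
* The REML search compares the interior Brent optimum against both interval
  bounds and the exact boundary $\lambda = 0$; LRT is floored at 0.
* Monomorphic markers are dropped from the GRM with a warning (error if all
  are); missing dosages are mean-imputed on read with a logged count.
* Peak-SNP ties on p break to the smaller position; BH q-values saturate at
  1, so degenerate thresholds (fdr = 1) are exercised through the partition
  identity rather than universal significance.
* Constant vectors in correlation layers are skipped with a warning, never
  propagated as NaN.
* Reals are written to TSV at 12 significant digits; BED output is 0-based
  half-open while all internal coordinates are 1-based inclusive.

## Known limitations

Standard errors for $h^2$ come from the curvature of the profile restricted
likelihood and are reported only away from the boundary. The boundary-mixture
LRT is slightly conservative when $G$ has limited eigenvalue spread (few
effective genetic dimensions), which is visible in null calibration near the
lower edge of its band. Proximal contamination — the causal SNP's own
contribution to $G$ — attenuates backsolved t-statistics relative to a
leave-one-chromosome-out design, which is not implemented. One SNP is
conditioned on at a time; stepwise multi-SNP conditioning is out of scope.
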