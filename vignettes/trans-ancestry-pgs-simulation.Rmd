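---
title: "Simulating the transferability of trans-ancestry polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the transferability of trans-ancestry polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Polygenic scores (PGSs) built from predominantly European-ancestry GWAS
transfer poorly to other ancestries, in part because allelic effect sizes
differ between populations.  `transpgs` simulates multi-ancestry
genotype–phenotype cohorts with controllable cross-ancestry effect-size
heterogeneity and measures, per target ancestry, how much phenotypic
variance four score constructions recover:

* **AS** — ancestry-specific: a fixed-effects meta-analysis restricted to
  the target ancestry's own studies;
* **FETA** — fixed-effects trans-ancestry meta-analysis over all studies;
* **RETA** — DerSimonian–Laird random-effects trans-ancestry meta-analysis;
* **TAMR** — trans-ancestry meta-regression of per-study effects on axes of
  genetic variation, yielding ancestry-aware per-population weights.

This vignette documents the generative model, the estimators, the
numerical choices, and what the simulations do and do not say about real
data.

## The generative model

**Population structure.**  Populations are defined solely by a frequency
panel: effect-allele frequencies for independent variants in 20
subpopulations grouped into five continental ancestries (AFR, AMR, EAS,
EUR, SAS; four subpopulations each), mirroring the 1000 Genomes sampling
design.  A panel can be loaded from a pre-exported frequency TSV or
synthesized with `synthesize_panel()`, which draws a two-level
Balding–Nichols hierarchy: per variant an ancestral frequency
$p_0 \sim U(0.05, 0.95)$; per ancestry
$p_a \sim \mathrm{Beta}$ with mean $p_0$ and variance
$F_a\,p_0(1-p_0)$; per subpopulation $p_s$ analogously around $p_a$ with
$F_s$.  Defaults $F_a = 0.1$, $F_s = 0.01$ are rough magnitudes of
continental versus within-continent differentiation.  Boundary draws are
clamped to $[0.001, 0.999]$ so every variant stays polymorphic somewhere.
`filter_common()` then drops variants whose ancestry-level minor allele
frequency (unweighted mean of the ancestry's subpopulation frequencies) is
below 1% in *all* ancestries; the stricter "common in every ancestry"
reading is available as `mode = "all"`.  The unweighted mean is
appropriate because subpopulations within an ancestry always receive equal
sample sizes here.

**Genotypes.**  Within a subpopulation, allele counts are
$g_{ij} \sim \mathrm{Binomial}(2, p_j)$ independently across variants and
individuals (Hardy–Weinberg equilibrium, no linkage disequilibrium: the
variants model independent clumped index SNPs, not a contiguous genome).

**Effects and heterogeneity.**  For $N_{\mathrm{SNP}}$ causal variants,
effect magnitudes are i.i.d. log-normal (natural-log parameters
$\mu = -3$, $\sigma = 1$ by default) with random signs; the log-normal is
a standard model for common-variant effect magnitudes, and the location
parameter is immaterial after the heritability rescaling below.  A
uniformly random subset of $\mathrm{round}(P_{\mathrm{HET}} \cdot
N_{\mathrm{SNP}})$ variants is *heterogeneous*: each carries its effect in
exactly one ancestry (chosen uniformly at random, or fixed via
`het_ancestry`) and is null in the others, re-using the same signed
magnitude rather than re-drawing it.  Homogeneous variants share one
effect across all five ancestries.  Each ancestry column $a$ of the
effect matrix is then rescaled by

$$c_a = \sqrt{h^2 \Big/ \sum_j 2\,\bar p_{ja}(1-\bar p_{ja})\,\beta_{ja}^2}$$

so that the expected genetic variance equals $h^2_{\mathrm{SNP}}$ in
*every* ancestry (heritability is treated as equal across ancestral
populations).  A consequence worth knowing: because $c_a$ differs slightly
across ancestries, a "homogeneous" variant's scaled effects are identical
across ancestries only up to these per-column constants; and under high
$P_{\mathrm{HET}}$ the carriers of a given ancestry are fewer, so their
individual effects are scaled *up* to preserve that ancestry's $h^2$.

**Phenotypes.**  $y_i = \sum_j (g_{ij} - 2\bar p_j)\beta_j +
\varepsilon_i$ with $\varepsilon_i \sim N(0, 1 - h^2)$, where $\bar p_j$
is the ancestry-level mean frequency — centring keeps the phenotype mean
near zero without leaking subpopulation labels.  Disease liability (the
T2D preset) is simulated as this continuous trait; there is no
case/control dichotomisation.

**Study design.**  The same generative draw is used twice: a *base*
cohort, on which per-subpopulation GWAS are run to estimate and select
effects, and an independent *target* cohort, on which the scores are
evaluated.  Both default to 150,000 individuals.
$\mathrm{round}(P_{\mathrm{EUR}} \cdot n)$ individuals go to the European
ancestry and the remainder is split equally over the four non-EUR
ancestries, then equally over each ancestry's subpopulations
(floor-then-distribute in fixed order, so totals are exact and
deterministic).

## Estimation and scoring

**GWAS.**  Per variant, ordinary least squares of phenotype on allele
count with intercept, p-values from the $t_{n-2}$ distribution (the exact
small-sample choice; at the default $n$ it is indistinguishable from the
normal).  No covariates are needed because subpopulations are internally
unstructured by construction.  Monomorphic variants are reported with
$\mathrm{SE} = \infty$, $p = 1$, so they carry zero meta-analytic weight
while keeping variant alignment across studies.

**Meta-analyses.**  With per-study estimates $\hat\beta_k$ and weights
$w_k = 1/\mathrm{se}_k^2$: the fixed-effects combination is
$\hat\beta_{FE} = \sum w_k \hat\beta_k / \sum w_k$ with
$\mathrm{SE} = (\sum w_k)^{-1/2}$ and Cochran's
$Q = \sum w_k(\hat\beta_k - \hat\beta_{FE})^2$; the random-effects
combination uses the DerSimonian–Laird moment estimator
$\hat\tau^2 = \max\{0, (Q - (K-1)) / (\sum w_k - \sum w_k^2/\sum w_k)\}$
and re-weights by $1/(\mathrm{se}_k^2 + \hat\tau^2)$ (method of moments;
no REML).  The ancestry-specific analysis is the fixed-effects combination
restricted to the four studies of one ancestry.

**Axes of genetic variation.**  The pairwise distance between two studies
is the mean squared difference of their allele frequencies over the panel
variants; classical metric multidimensional scaling (double-centring plus
eigendecomposition) of this matrix gives per-study coordinates, ordered by
eigenvalue and sign-fixed so each axis's largest-magnitude loading is
positive.  This is the construction used by trans-ancestry meta-regression
software; a PCA alternative (`axes_method = "pca"`) gives equivalent
ancestry separation.  The default $T = 3$ axes is the smallest number that
separates five ancestry clusters among 20 studies and leaves ample
residual degrees of freedom ($T \le K - 2$ is enforced).  Axes are
computed from the panel's true frequencies by default — the noiseless
analogue of deriving them from reference genotypes.

**Meta-regression.**  Per variant, weighted least squares of
$\hat\beta_k$ on $[1, x_{k1}, \dots, x_{kT}]$ with weights $w_k$.  With
error variances treated as known, the coefficient covariance is the
inverse normal-equations matrix, giving three chi-square statistics: the
joint association Wald test on $T+1$ df (used for variant selection), the
ancestry-correlated heterogeneity test on the axis coefficients ($T$ df),
and the residual heterogeneity (weighted residual sum of squares,
$K - T - 1$ df).  The last two partition the intercept-only Cochran $Q$
exactly — a property the test suite asserts to $10^{-8}$.

**Scores.**  Each method selects variants with association $p$ strictly
below $5\times10^{-8}$ under its own test and weights them with its own
combined effect; TAMR weights are the fitted regression evaluated at each
target subpopulation's axis coordinates (base and target share the same
20 subpopulations; projecting external populations onto the axes is out
of scope).  A score that selects no variant is defined to explain zero
variance.  Direct evaluation is the squared Pearson correlation between
score and phenotype in the target subpopulation.  Indirect evaluation
approximates it from target summary statistics under independent variants
and unit trait variance:
$r^2 = \big(\sum_j w_j\,2p_j(1-p_j)\,\hat b_j\big)^2 \big/ \sum_j
w_j^2\,2p_j(1-p_j)$, clipped to $[0,1]$; the formula is isolated in
`evaluate_indirect()` so it can be swapped if a different approximation is
preferred.  Reported ancestry values average the four subpopulations per
replicate; points are means over replicates with the standard error of the
mean across replicates.

## Reproducibility and numerical choices

Every cell of a scenario grid is seeded by `cell_seed(master, p_het,
p_eur, replicate)`, a fixed multiplicative mix modulo $2^{31}-1$, so grids
are pure functions of (panel, config, master seed), adding grid points
never perturbs existing cells, and interrupted grids resume
bit-identically from per-cell TSVs.  Other numerical conventions:
p-values are floored at the smallest positive double rather than
underflowing to zero; weighted normal equations are solved by Cholesky
factorisation with rank-deficient designs flagged per variant rather than
failing the run; $\hat\tau^2$ is truncated at zero; genotype blocks are
simulated, used, and discarded one subpopulation at a time so peak memory
stays at one block (about 75 MB at the default design) rather than a full
cohort.

## Problem sizes used by the test suite

The packaged tests exercise the headline heterogeneity comparison (500
causal SNPs, $h^2 = 0.5$, $P_{\mathrm{EUR}} = 0.5$, $P_{\mathrm{HET}} \in
\{0, 0.5\}$) and the two trait presets at the full 150,000/150,000 design
with 10 replicates, and the European-share sweep for the
ancestry-specific score at 30,000/30,000 — sizes chosen so the whole
suite completes in well under half an hour on one CPU while keeping the
headline cells at the reference design.  The trait presets run with 500
causal variants; the presets' polygenicity default (2,000) and especially
the consortium-scale sample sizes of the real studies are far larger, so
trait-preset results here are indicative of the mechanisms, not of
absolute real-trait accuracy.

## What the simulations do and do not show

The generator emulates ancestry-correlated allele-frequency drift,
equal-heritability architectures, and single-ancestry effect
heterogeneity.  It deliberately omits linkage disequilibrium, rare
variants, non-causal variants, case/control ascertainment, covariates,
relatedness, and within-subpopulation structure.  Consequences worth
keeping in mind when mapping results onto real data:

* Transferability is likely *over*-estimated, especially for African
  target populations, because LD differences and rare variants are absent.
* The ancestry-specific score's apparent sensitivity to
  $P_{\mathrm{HET}}$ at moderate sample sizes is a power phenomenon of
  this architecture: concentrating an ancestry's $h^2$ on fewer carrier
  variants makes them individually easier to detect, so AS accuracy can
  *rise* slightly with heterogeneity before power saturates.
* Under the uniform-carrier architecture, the heterogeneous variants of
  any one target ancestry hold roughly
  $P_{\mathrm{HET}}/(5 - 4P_{\mathrm{HET}})$ of that
  ancestry's genetic variance (about 1/6 at $P_{\mathrm{HET}} = 0.5$), which
  bounds how much accuracy a fixed-effects score can lose — and how much a
  heterogeneity-aware score can regain — relative to it.  Architectures
  that concentrate more variance in heterogeneous variants would widen
  these gaps.
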