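---
title: "Mapping sex-specific genetic architectures with local Bayesian regressions"
author: "lbrmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping sex-specific genetic architectures with local Bayesian regressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many complex traits differ between the sexes, and part of that difference
can come from autosomal loci whose allelic effects differ in males and
females (gene-by-sex, G×S, interactions). Individually these interactions
tend to be tiny, so one-SNP-at-a-time association scans with a
sex-heterogeneity test — the standard approach — are underpowered once the
multiple-testing burden is paid, and their marginal effect estimates
smear signal across long stretches of linkage disequilibrium (LD).

`lbrmap` takes the whole-genome-regression route instead: the phenotype is
regressed on many SNPs jointly, so each coefficient is conditional on its
LD neighbours, and sparsity-inducing priors let the data decide which SNPs
carry signal. Because a genome-wide joint fit at biobank scale is
impractical, the model is fit on long overlapping chromosome segments —
local Bayesian regressions — which capture local LD at a fraction of the
cost.

## The model

For a segment with genotype matrix split by sex into $X_m$ (males) and
$X_f$ (females):

$$
\begin{bmatrix} y_m \\ y_f \end{bmatrix} =
\begin{bmatrix} 1\mu_m \\ 1\mu_f \end{bmatrix} +
\begin{bmatrix} X_m \\ X_f \end{bmatrix} b_0 +
\begin{bmatrix} X_m \\ 0 \end{bmatrix} b_m +
\begin{bmatrix} 0 \\ X_f \end{bmatrix} b_f +
\begin{bmatrix} \varepsilon_m \\ \varepsilon_f \end{bmatrix},
$$

with sex-specific intercepts $\mu_m,\mu_f$, a shared effect $b_{0j}$ per
SNP, male and female interaction deviations $b_{mj}, b_{fj}$, and
residuals with sex-specific variances $\sigma^2_{\varepsilon m} \ne
\sigma^2_{\varepsilon f}$. Sex-specific effects are
$\beta_{mj} = b_{0j} + b_{mj}$ and $\beta_{fj} = b_{0j} + b_{fj}$.

Each effect class $k \in \{0, m, f\}$ has a spike-slab prior,
$$
\Pr(b_{kj}) = \pi_k\, N(0, \sigma^2_{bk}) + (1-\pi_k)\,\mathbb{1}(b_{kj}=0),
$$
with a Beta$(a_k, b_k)$ hyper-prior on $\pi_k$ and a scaled-inverse-
$\chi^2$ hyper-prior on the slab variance $\sigma^2_{bk}$. The point mass
matters: posterior draws contain exact zeros, which makes "the male and
female effects differ" a well-defined indicator event per draw, with no
epsilon thresholds.

### The Gibbs sweep

`gibbsFit()` runs a deterministic sweep per iteration:

1. intercepts from their Gaussian full conditionals (flat prior);
2. for each SNP in genomic order and class in the order $0, m, f$: the
   inclusion indicator from its effect-integrated Bernoulli conditional,
   then the effect from its Gaussian conditional if included, else an
   exact zero. The shared class uses heteroskedastic error-variance
   weights over all individuals (the residual variances differ by sex);
   the sex classes use their own sex's rows. Residuals are updated
   incrementally after every change;
3. slab variances from scaled-inverse-$\chi^2$ with df
   $\nu_k + m_k$ and scale sum $\nu_k S_k + \sum_{j \in \text{in}} b_{kj}^2$;
4. $\pi_k$ from Beta$(a_k + m_k,\; b_k + p - m_k)$;
5. residual variances from each sex's residual sum of squares.

SNP columns are centered on the pooled mean before sampling (pooled, not
per-sex, so the interaction deviations keep their interpretation as
departures from a common shared effect). The phenotype is scaled to unit
pooled variance but not centered — the intercepts absorb the sex means —
so every variance-scale output reads as a proportion of phenotypic
variance.

The sampler is validated two independent ways in the test suite: in the
conjugate limit ($\pi_k = 1$, variances pinned) its posterior means are
compared with the generalized ridge solution
$(Z'WZ + D)^{-1} Z'Wy$ computed by direct linear algebra, and on
two-SNP panels its inclusion probabilities are compared with exhaustive
enumeration of all 64 indicator configurations with the effects
integrated out analytically.

### Hyper-parameter defaults

The defaults (all overridable through `lbrPrior()`) follow common
whole-genome-regression practice:

* `slabDf = 5`; the slab scale is set so the prior-expected genetic
  variance of each class is one third of an overall trait $R^2$ guess
  (default 0.5), apportioned to a segment by its share of genome SNPs;
* `piA = 1`, `piB = p/50`: prior mean inclusion around 50 SNPs per class
  per segment — sparse, but weakly informative;
* `residualDf = 5` with scale matched to the phenotype variance.

MCMC defaults (`mcmcConfig()`) are 12000 iterations, 2000 burn-in,
thinning 5 — 2000 stored draws, giving posterior probabilities a Monte
Carlo standard error around 0.011. The workstation-scale runs in the
test-suite use shorter chains (typically 2000–3000 iterations, 300–500
stored draws) because the quantities checked there are coarse
(probability thresholds, rank orderings, correlations); those sizes are
stated in each test.

## Tiling and stitching

`planSegments()` divides each chromosome into disjoint core blocks of
1500 SNPs (the last core takes the remainder) and extends each by 250
buffer SNPs per side, clipped at chromosome ends — at typical human SNP
density, roughly 8 Mb cores with 1 Mb buffers, comfortably beyond the
1–2 Mb range where dosage $R^2$ dies off in unstructured populations.
Buffers exist only to shield core SNPs from edge effects; after fitting,
`stitchSamples()` keeps each SNP's samples from the unique segment whose
core owns it and discards buffer copies.

Draw $t$ of every segment is treated as draw $t$ of the stitched
genome-wide sample. The segments are statistically independent fits, so
this positional alignment is a modelling convenience; it is harmless for
any functional that involves SNPs from one segment at a time, and for
windows straddling a core boundary it assumes cross-segment posterior
dependence is negligible beyond the buffer span — the same assumption
that justifies tiling at all. The acceptance suite checks it directly:
on one simulated chromosome, per-SNP posterior means from a stitched
tiled fit correlate above 0.95 with a single joint fit.

Segments are fit independently with per-segment seeds derived
deterministically from the global seed and segment index, so results do
not depend on execution order and parallel dispatch is safe.

## Inference outputs

**SNP level** (`snpProbabilities()`): posterior means of
$\beta_m, \beta_f$; `PPM`/`PPF`, the posterior probabilities of a
nonzero male/female effect; `PPDiff`, the probability the two differ —
by the point mass, the fraction of draws in which the interaction
deviations are not both zero; and `PP_any = max(PPM, PPF)`.

**Window level**: single-SNP inference is fragile inside strong LD, so
effects are aggregated over small LD-defined windows. For each focal SNP
$j$, `defineWindow()` extends left and right while the squared dosage
correlation with the focal SNP stays at or above `r2Threshold` (default
0.05), stopping at the first failure (`gapTolerance = 0`), at 1 Mb, or
at the chromosome end. This yields heavily overlapping, dynamically
sized windows, one per focal SNP. The exact rule is a design choice of
this package; every parameter is exposed.

Per draw and window, `windowVariances()` computes
$\sigma^2_{g} = \mathrm{var}(X_{j^*}\beta_{j^*})$ — the sample variance
(denominator $n-1$) of the window's genetic values over all individuals,
using pooled-centered dosages. Pooled rather than per-sex genotype
matrices are used because window variances are read against the pooled
phenotypic variance (a per-sex variant is available via subsetting the
panel). On the unit phenotype scale these are proportions of variance
explained. `PPMvar`/`PPFvar`/`PPDiffVar` are again exact indicator
events: a window variance is nonzero in a draw iff some sex-specific
effect in the window is nonzero, and the male/female variances differ
iff some interaction deviation in the window is nonzero (otherwise
$\beta_m \equiv \beta_f$ there). A limitation inherited by any
variance-scale summary: the sign of the sex difference is lost.

Implementation note: window variances are evaluated as quadratic forms
$\beta_w' S_w \beta_w$ against per-chromosome dosage covariance
matrices, exploiting the exact zeros of spike-slab draws so the cost
scales with the number of included effects, not the window width. Draws
with no included SNP in a window give exactly zero, and draws where
$\beta_m = \beta_f$ within the window give bitwise-equal variances.

## The single-marker baseline

`smrScan()` implements the standard comparison scan: per
sex, simple regression of the scaled phenotype on dosage; sex difference
tested with $z = (\hat\beta_f - \hat\beta_m)/\sqrt{se_f^2 + se_m^2}$
against the standard normal; and a 2-df any-sex test from
$z_m^2 + z_f^2 \sim \chi^2_2$, valid because the sexes are disjoint
samples (at these sample sizes the distinction from an F reference is
negligible). No covariates: phenotypes are assumed precorrected
upstream. SNPs monomorphic within a sex get p-values of 1 and a flag.

## The simulator

`simulateGenotypes()` uses a latent-Gaussian haplotype model: exponential
inter-SNP spacings (default mean 5 kb), a stationary first-order latent
process per haplotype with correlation $\exp(-d/\phi)$, and allele
indicators thresholded at the $1-\mathrm{maf}$ quantile, maf uniform in
[0.05, 0.5]; dosage is the sum of two independent haplotypes. $\phi$ is
calibrated so $\exp(-2d/\phi) = 0.01$ at `ldDecayBp` (default 1.5 Mb);
binarisation only attenuates further, so dosage $R^2$ is below 0.01
beyond that distance — the one property of real panels the local
regression strategy leans on. What this generator does *not* emulate:
coalescent block structure, allele-frequency/LD coupling, population
structure or relatedness. Tests passing on it therefore speak to the
statistical machinery under realistic LD *scale*, not to robustness
against confounding.

`simulateTrait()` places causal variants one per 2 Mb stratum (uniformly
within a stratum), each with expected variance contribution
`perVariantR2` (default $3.3\times 10^{-4}$), 40% of them with
sex-differing effects. Shared variants get equal per-sex effects of
magnitude $\sqrt{r^2/\mathrm{var}(x)}$ (random sign) using the expected
HWE dosage variance $2\hat p(1-\hat p)$, so the *realized* fraction
(sample variance of the contribution) fluctuates around the target.
Sex-differing variants follow `gxsScheme`: `one_sex_only` doubles the
variance in the active sex (alternating) so the pooled contribution
stays at $r^2$; `independent_draw` draws per-sex effects independently
with equal expected per-sex variance; `mixed` (default) is half each —
the generating scheme is a design choice, exposed and recorded.

Two bookkeeping choices keep the variance accounting exact. Genetic
contributions are centered within sex before forming the genetic value:
real phenotypes are sex-precorrected upstream, so a between-sex genetic
mean shift is not trait variance (leaving it in would inflate realized
per-variant fractions of one-sex effects by tens of percent). And the
residual vector is projected orthogonal to the genetic values and
rescaled, so realized genetic + residual variance equals total variance
to machine precision before the final unit scaling.

`deskPreset()` is the workstation design used throughout the heavier
tests: 3000 individuals per sex, 2 chromosomes × 1000 SNPs at 5 kb
spacing (10 Mb), 10 causal variants — one per 1 Mb stratum, the spacing
that fits exactly 10 strata into 10 Mb — 4 of them sex-differing, with
per-variant $r^2$ inflated to $2\times 10^{-3}$ so power is estimable at
this sample size. `paperScalePreset()` keeps the full biobank-scale
design (119,190 males, 139,738 females, 60,000 SNPs, 150 causal, per-
variant $3.3\times 10^{-4}$); it is cluster-scale and not intended for a
workstation.

## Power/FDR evaluation

`powerFdrObserved()` scores selections against the causal truth when
causal variants are genotyped. `powerFdrTargetArea()` handles the
masked-causal regime (`maskCausal()` removes causal columns): a
selection tags a causal variant if it — or any SNP of a selected window —
lies within the target-area half-width (full areas 1 Mb, 500 kb,
250 kb); power is the fraction of sex-differing variants tagged, FDR the
fraction of selections tagging none. FDR with zero selections is defined
as 0 (avoids 0/0; irrelevant at any realistic operating point).
`mergeWindows()` collapses window selections sharing SNPs into distinct
regions before counting. `mcAggregate()` turns per-replicate curves into
means with normal-approximation 95% intervals. `hypergeomEnrichment()`
is the upper-tail hypergeometric test used to ask whether selected focal
SNPs are enriched in an annotation (e.g. eQTL) id set.

The conventional operating points — `PPDiff` $\ge 0.95$/$0.90$,
`PP_any` $\ge 0.95$, $p \le 5\times 10^{-8}$ — are bundled in
`operatingPoints()`.

## Numerical and degenerate-input choices

* Zero/equality events always use the stored exact zeros; no tolerances.
* Monomorphic columns get a zero-precision guard in the sampler (effect
  stays at its exact zero) and collapse windows to the focal SNP with a
  warning.
* Missing dosages are mean-imputed per SNP pooled across sexes
  (frequency-preserving); an all-missing SNP is an error naming the SNP.
* Constant phenotypes cannot be scaled and error out.
* Chain diagnostics (`logDiagnostics()`) report batch-means Monte Carlo
  standard errors and split-chain potential scale reduction for the
  residual variances and inclusion proportions.
* Non-finite residuals abort the sampler with the iteration index.

## Known limitations

* Autosomes only; no X-chromosome dosage model.
* No covariates inside the model or the scan: phenotypes must be
  precorrected.
* Positional draw alignment across segments (above) is assumed, not
  modelled.
* The genotype simulator's LD is stationary and unstructured; power/FDR
  numbers transfer to real panels only qualitatively.
* Window variances cannot distinguish same-sign from opposite-sign
  sex differences.
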