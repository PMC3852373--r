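---
title: "Spatial adjustment of field trials and genomic prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial adjustment of field trials and genomic prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spatgs)
library(dplyr)
```

spatgs implements a genomic-selection workflow for inbred-line field trials
in which plot-level phenotypes carry strong spatial trends: marker quality
control and imputation, four competing phenotypic adjustment models, REML
variance components and broad-sense heritability, and GBLUP genomic
prediction with additive and Gaussian kernels evaluated by replicated
cross-validation and cross-environment training. A synthetic generator with
known truth provides the test surface for every stage. This vignette
explains the models, the tunable parameters, and the design decisions that
were genuinely open.

## Phenotypic adjustment models

A trial is a tibble of plots: `genotype`, `rep`, `block`, `row`, `col` and a
trait value `y`. Four models turn plot values into per-genotype adjusted
values (BLUPs):

* **IB** — the field design itself: `y = g + rep + block(rep) + e`, all
  factors random, fitted by REML.
* **RC** — row-by-column: `y = g + rep + row(rep) + col(rep) + e`.
* **RCB_MVNG** — randomized complete blocks with the moving-means covariate
  `x` as a fixed regression: `y = g + beta * x + rep + e`.
* **MVNG** — a two-stage procedure: ordinary regression `y = mu + beta * x + e`,
  the spatially adjusted plot value being `mu + residual`; then a
  random-genotype model on the adjusted values yields BLUPs and
  heritability. The second stage exists because the regression model itself
  contains no genotype term, yet adjusted genotype means and a heritability
  are needed downstream.

All non-genetic design factors are treated as random, and genotype is
random throughout: BLUPs and broad-sense heritability require a genotype
variance component, and nothing in the models' specification forces any
factor to be fixed.

### The moving-means covariate

The covariate for plot *i* is built from its grid neighbours within the
same replicate. The default neighbourhood is the two same-row plots plus
the four diagonal plots of the adjacent rows — six neighbours, a sensible
choice when plots are long and thin so that same-row neighbours share the
most micro-environment. Offsets are configurable (`moving_grid()`).
Unphenotyped or out-of-replicate positions are simply dropped; plots with
fewer than `min_neighbors` (default 2) usable neighbours get a neutral
covariate value and a flag. Discarding border plots instead would lose
roughly 15% of a typical grid, which is why the fallback exists.

Two covariate definitions are supported. `covariate = "neighbor_mean"`
(the default) uses the mean phenotype of the neighbours — the classical
moving-means covariate. `covariate = "deviation"` uses the plot value minus
that mean. The deviation form is sometimes written as the definition of the
covariate, but it cannot be what a working adjustment uses: regressing `y`
on `y - neighbour mean` yields a slope near `k/(k+1)` for `k` neighbours
(about 0.86 with six), and the "adjusted" value `y - beta*x` then *keeps*
the spatial trend while shrinking the genetic signal roughly `(k+1)`-fold —
heritability collapses instead of rising. With the neighbour-mean covariate
the slope captures how strongly the local trend predicts the plot, and
`y - beta*x` removes trend while leaving the plot's own genetic deviation
untouched. The deviation form is therefore provided for completeness and
the neighbour mean is the default.

### Heritability

Broad-sense heritability is reported on an entry-mean basis,

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e / r},$$

with `r` the number of replicates (2 in the emulated design), clamped to
[0, 1]. For the two-stage MVNG model the stage-2 components are used; the
RCB_MVNG and MVNG estimates are typically indistinguishable, which is why a
single column can summarize both.

### Residual diagnostics

`residual_field_map()` arranges per-plot residuals on the grid and reports
Moran's I with a permutation p-value (999 permutations by default), using
binary rook adjacency between occupied cells. A model that has absorbed the
trend leaves residuals with Moran's I near zero; a model that has not
(typically RC under a smooth trend) leaves strongly positive
autocorrelation. With 768 plots even a tiny residual I can be formally
significant, so the magnitude of I, not only its p-value, is the diagnostic
to read.

## The REML engine

`reml_fit()` handles Gaussian mixed models with an arbitrary number of
independent random factors, each optionally carrying a known covariance
matrix among its levels (used for kernel terms). Numerics, in order of
preference:

* **One random term** — the restricted likelihood is profiled exactly over
  the variance ratio `lambda = sigma2_e / sigma2_u` on the log scale
  (bounded scalar minimisation, tolerance 1e-8); this is fast and has no
  convergence failures.
* **Several terms** — EM-REML on Henderson's mixed-model equations (at most
  40 iterations; each iteration provably does not decrease the restricted
  likelihood) followed by a Nelder-Mead polish of the restricted
  likelihood on the log-variance scale. Components are clamped at a 1e-10
  floor where the unconstrained optimum would be negative.
* Aliased fixed-effect columns are dropped deterministically left to right.

`gblup_fit()` is the single-kernel special case solved by spectral
decomposition of the training submatrix of `K`; predictions for unobserved
lines are `K[test, train] (K[train, train] + lambda I)^{-1} (y - mu)`. The
additive-kernel version is algebraically identical to ridge regression on
marker effects with penalty `c * lambda`, and the package's test suite
checks that identity to 1e-6, as well as agreement of the whole engine with
lme4 on models both can fit.

## Kernels and prediction

* **RR** (additive): `A = (G - P)(G - P)' / c` with column-mean centring
  and `c = sum(2 p_k (1 - p_k))`, so fully inbred panels have mean diagonal
  near 2.
* **GAUSS**: `K_ij = exp(-(d_ij / theta)^2)` on Euclidean marker distances
  scaled by their mean, making `theta` unitless. The default
  `theta = "profile"` selects the bandwidth per training set by restricted
  likelihood over a 21-point log-grid on [0.1, 10]; profiling is done
  inside each training fold so no information from held-out lines leaks
  into the choice. A fixed unit bandwidth is a poor default: on epistatic
  traits it can *underperform* the additive kernel, while the profiled
  bandwidth adapts.

Cross-validation follows the replicated random-partition design:
each replicate splits the lines into 7 sets whose sizes differ by at most
one (so 384 lines train on 86% and validate on 14%), every set validates
once, fold accuracy is the Pearson correlation between predicted genetic
values and observed adjusted phenotypes, the replicate accuracy is the mean
over folds, and the report is the mean and SD over replicates (100 by
default). `compare_adjustments()` reuses identical partitions across
adjustment models and kernels so columns are paired replicate by replicate.
Pearson correlation is used throughout; accuracy is invariant to affine
rescaling of the response.

For cross-environment training, each training environment's per-genotype
values are standardized to zero mean and unit variance and averaged into a
single training response; GBLUP is then fitted on all genotypes and
accuracy is the correlation with the test environment's adjusted values.
Standardizing before averaging is the simplest faithful reading of "train
on the adjusted data of several environments" when no environment-effect
model is specified.

## Genotype quality control

`filter_markers()` applies three per-marker rules: minor allele frequency
at least 0.01 (boundary kept; heterozygotes count half an allele),
missingness at most 80%, and an inbreeding coefficient
`F = 1 - Hobs/Hexp >= 0.9` — equivalently observed heterozygosity at most
one tenth of the Hardy-Weinberg expectation — which purges spurious
heterozygote calls in panels of highly homozygous lines. Monomorphic
markers fail the MAF rule.

`impute_mvn_em()` fills missing calls with conditional expectations under a
multivariate-normal model across lines whose covariance is the realized
relationship matrix, iterating imputation and relationship re-estimation to
a 1e-4 tolerance on imputed values (at most 100 iterations; the
relationship matrix carries a 1e-6 diagonal regularization). Observed calls
are never altered and imputed values are clamped to [-1, 1]. Whether
kinship and PCoA downstream use imputed or raw data is the caller's choice;
imputed is the default recommendation.

PCoA is classical metric scaling of the allele-sharing dissimilarity;
negative eigenvalues are discarded (no Cailliez correction) because only
the leading coordinates and their percentages of variance are consumed.
LD is the squared Pearson correlation of genotype codes over jointly
observed lines, valid for inbred biallelic data; pairs are caller-supplied
because no genetic map is assumed.

## The synthetic generator

`sim_config()` defaults describe the emulated study: 384 inbred lines from
2 breeding programs, an alpha-lattice with 20 incomplete blocks of up to 20
genotypes and 2 replicates laid on a 32 x 24 grid (768 plots), several
thousand independent biallelic markers, and a smooth spatial trend over the
field. Specific choices:

* **Genotypes** are fully homozygous draws from subpopulation allele
  frequencies that drift from common ancestral frequencies under a
  Balding-Nichols model (`subpop_divergence = 0.2` by default, an Fst-like
  quantity giving clear but overlapping program structure).
* **Spatial surface** = equal-variance mix of a second-order polynomial in
  scaled (row, column) — all five terms with equal variance and random
  signs, so every realization contains both row- and column-direction
  gradients — and a separable AR(1) x AR(1) Gaussian field with
  correlation 0.6 per step, reproducing a global gradient plus patchiness.
  Its variance is `spatial_var_ratio` times the iid plot-error variance.
* **Calibration**: the reference operating point for a strong-trend yield
  trial is `spatial_var_ratio = 4` with plot-basis heritability
  `h2_plot = 0.55`; under the incomplete-block analysis this yields
  entry-mean heritability near 0.4, and the moving-means model recovers
  substantially more (the acceptance script recomputes both). Replicate
  and block variances default to 5% and 10% of the plot-error variance —
  modest design effects.
* **Epistasis** follows a multiplicative additive-by-additive model: the
  effect of a marker pair is the product of the two markers' additive
  effects, so the epistatic deviation is the standardized quadratic
  component of the centred additive score and carries `epistasis_fraction`
  of the unit genetic variance. With independent random pair effects
  instead, the epistatic kinship of an essentially unrelated panel is
  near-diagonal and the epistatic variance is unpredictable by
  construction — no kernel could then be expected to exploit it.
* **Layout**: genotypes are dealt into blocks of near-equal size by
  within-replicate randomization; no optimal alpha-design algorithm is
  used, which matters for design efficiency but not for testing the
  analysis machinery. One trait per call; simulate repeatedly over shared
  genotypes for multiple traits.

What the generator does **not** emulate: linkage disequilibrium among
markers, pedigree/family relatedness beyond subpopulation drift,
genotype-by-environment interaction within a trial, and non-Gaussian plot
error. Two practical consequences. First, kinship-fidelity checks (split
halves, imputation) need more markers than a real GBS panel would to reach
the same signal-to-noise, because real panels add family-level relatedness
variance. Second, the small, consistent advantage of the Gaussian kernel
over the additive kernel seen on real data reproduces here only in most
panels, not all: in a minority of synthetic panels the realized epistatic
component is genuinely unpredictable out of sample (verifiably so — its
own cross-validated accuracy is near zero under any kernel), the profiled
bandwidth correctly collapses to the additive limit, and the two kernels
tie. Passing or failing that comparison on a single synthetic panel says
little about real GBS data; the acceptance machinery therefore evaluates
it across 20 independent panels, and a shortfall there reflects this known
limit of the synthetic world rather than a defect of the kernels.

## Problem sizes and runtime

The shipped tests and the acceptance script use scaled-down sizes chosen to
keep every stage exact but quick: panels of 40-384 lines, 10-2000 markers
(40,000 only for the split-half kinship check, where marker count drives
the signal-to-noise of the comparison), 20 cross-validation replicates
instead of 100, and 20-50 simulation seeds per property. These sizes are
the package's own choices for its reference checks; all of them rerun in a
few minutes on a single core, and all scale parameters are exposed if
larger studies are wanted.

## Known limitations

* No spline or separable-autoregressive residual modelling; the four
  models above are the scope, and the moving-means covariate is the only
  spatial device.
* The REML engine fits independent random factors (optionally with known
  level covariances), not correlated residual structures or multi-trait
  models.
* The LD utility takes caller-supplied pairs; it does not order markers on
  a map.
* Only biallelic, essentially homozygous genotype data are supported; the
  VCF importer skips multiallelic sites and codes heterozygotes as 0.
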