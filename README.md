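# spatgs — spatial adjustment of field trials and genomic selection

Breeding programs that train genomic-prediction models on field-trial data
face a phenotyping problem before a genotyping one: plot yields and other
traits carry smooth spatial trends (soil, water, fertility gradients) that
inflate the error variance, depress heritability, and cap the accuracy any
marker-based model can reach. `spatgs` is an R package for exactly this
workflow on panels of inbred lines:

* **Marker QC and imputation** — minor-allele-frequency, missingness and
  inbreeding filters; EM imputation of missing genotypes under a
  multivariate-normal line model using the realized relationship matrix;
  allele-sharing kinship, principal-coordinate analysis and LD r².
* **Spatial adjustment** — four competing plot-level models fitted by a
  built-in REML engine: incomplete blocks (`IB`,
  `y = g + rep + bl(rep) + e`), row-by-column (`RC`,
  `y = g + rep + fil(rep) + col(rep) + e`), a mixed model with the
  moving-means covariate (`RCB_MVNG`, `y = g + βx + rep + e`), and a
  two-stage regression adjustment (`MVNG`, `y = u + βx + e` followed by a
  random-genotype model on the adjusted values). The covariate `x` is built
  from each plot's six grid neighbours. Broad-sense heritability
  `H² = σ²g / (σ²g + σ²e/r)` and residual field maps with Moran's I
  diagnostics summarize each fit.
* **Genomic prediction** — GBLUP with the additive (ridge-regression, RR)
  kernel `A = (G−P)(G−P)′/Σ2p(1−p)` and the Gaussian kernel
  `K_ij = exp(−(d_ij/θ)²)` with a REML-profiled bandwidth; replicated
  7-fold cross-validation (86% train / 14% validation) with paired fold
  randomizations across models and kernels; cross-environment training on
  standardized multi-environment means.
* **A synthetic study generator** — inbred genotypes with breeding-program
  structure, additive (optionally multiplicative add×add epistatic) genetic
  values, and alpha-lattice field trials with a known spatial surface, so
  every stage has a parameter-recovery test.

Results come back as tibbles (with `tidy()`/`glance()` methods on every
fitted object and `autoplot()` methods for maps, ordinations and accuracy
distributions), so the whole pipeline composes with dplyr and ggplot2.

## Worked example

Simulate a 384-line trial (two replicates, 20 incomplete blocks, a strong
spatial trend), adjust it with the design model and the moving-means model,
and compare their cross-validated GBLUP accuracies with paired partitions:

```r
library(spatgs)
library(dplyr)

cfg <- sim_config(n_markers = 2000, seed = 42)
sim <- simulate_trial_data(cfg)

ib <- fit_spatial_model(sim$trial, model = "IB")
mv <- fit_spatial_model(sim$trial, model = "MVNG")
bind_rows(glance(ib), glance(mv))
#> # A tibble: 2 × 6
#>   model    H2 sigma2_g sigma2_e loglik_restricted n_genotypes
#>   <chr> <dbl>    <dbl>    <dbl>             <dbl>       <int>
#> 1 IB    0.346    0.930     3.52            -1682.         384
#> 2 MVNG  0.520    1.10      2.03            -1504.         384

residual_field_map(ib)
#> Residual field map (IB) 32 x 24; Moran's I = 0.461 (p = 0.001)
residual_field_map(mv)
#> Residual field map (MVNG) 32 x 24; Moran's I = 0.0341 (p = 0.094)

cmp <- compare_adjustments(sim$trial, G = sim$genotypes,
                           specs = list(kernel_spec("RR")),
                           n_cv_reps = 20, seed = 1)
cmp
#> Paired cross-validation accuracy by adjustment model and kernel:
#> # A tibble: 1 × 5
#>   kernel IB              MVNG            RC              RCB_MVNG
#>   <chr>  <chr>           <chr>           <chr>           <chr>
#> 1 RR     0.088 +/- 0.020 0.228 +/- 0.023 0.238 +/- 0.021 0.229 +/- 0.023
```

Reading the numbers: the design model leaves the trend in its residuals
(Moran's I = 0.46, permutation p = 0.001) and estimates an entry-mean
heritability of 0.35; the moving-means adjustment removes the residual
autocorrelation (I = 0.03, p = 0.09), raises heritability to 0.52, and more than doubles
the cross-validated prediction accuracy (0.09 → 0.23, mean ± SD over 20
paired randomizations). `autoplot(residual_field_map(ib))` draws the
residual heat map; `tidy(cmp)` returns the per-replicate accuracies.

Field data enter through `read_phenotype_csv()` /
`read_genotype_tsv()` / `import_vcf()`; adjusted BLUPs and accuracy tables
leave through `write_blup_csv()` and `write_report_csv()`.

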