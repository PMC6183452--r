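# pigeonscape

Joint ecological and genomic inference for urban commensal birds.

Urban pigeons (and commensal birds generally) are managed with two
questions in mind: *how many are there, and where?* and *how far do they
move?* `pigeonscape` implements the full analysis chain used to answer
both from island-wide field data:

1. **Hierarchical distance sampling** for point-transect surveys.
   Site-level cluster abundance is Poisson with log-link covariates
   (feeding intensity *F*, landscape class *L*), detection is hazard-rate
   `g(r) = 1 − exp(−(r/σ)^−b)` with a log-linear model on σ, and the two
   are fitted jointly by maximum likelihood on binned radial distances
   (`μ_ij = λ_i · πB²/10⁴ · π_ij`). Candidate covariate structures are
   compared by AIC, the best model is projected onto a raster of ~1 km²
   cells, multiplied by the mean observed cluster size, and summed into
   an island total with a delta-method interval.
2. **Individual-based population genomics** from 0/1/2 SNP matrices:
   expected/observed heterozygosity and F_IS, windowed LD pruning,
   maximum-likelihood pairwise relatedness (k₀, k₁, k₂ over the IBD-mode
   simplex; `r = k₁/2 + k₂`), kin filtering at r > 10%, squared
   codominant genotypic distance, and PCA.
3. **Spatial genetic autocorrelation**: the multilocus correlogram
   `r(h)` over even distance classes (default 15 × 2 km), with a 999-
   permutation null envelope, 999 pair bootstraps, heterogeneity tests,
   and the two patch-size intercepts (where r(h) crosses zero and where
   it first enters the null envelope). A sex-stratified comparison calls
   sex-biased dispersal from overlapping bootstrap intervals.
4. **Isolation-by-distance residual mapping**: pairwise genetic distance
   is regressed on geographic distance; residuals are interpolated at
   pair midpoints onto the study grid (moving-window IDW). Positive
   accumulations mark dispersal barriers, negative mark corridors;
   per-cell significance comes from residual randomization and per-cell
   power from individual bootstraps, and the surface is correlated
   against landscape covariate rasters.

A synthetic-data generator (`gen_covariates`, `simulate_surveys`,
`gen_samples`, `simulate_genotypes`) produces covariate rasters,
surveys and spatially structured genotypes with *known truth*
(abundance coefficients, detection parameters, genetic patch size,
planted barriers, injected kin), so every stage is testable by
parameter recovery.

## Worked example

```r
library(pigeonscape)

rasters <- gen_covariates(seed = 101)               # F, L, P, R on 25 x 50 grid
survey  <- simulate_surveys(truth_config(), rasters,
                            n_sites = 400, seed = 102)

cluster_size_summary(survey)
#>   s_bar n_clusters kw_stat kw_df  kw_p
#> 1  3.74      10895    2.41     4 0.660

fits <- list(
  null    = hds_fit(survey, abundance = ~1, detection = ~1),
  L       = hds_fit(survey, abundance = ~landscape, detection = ~1),
  FL      = hds_fit(survey, abundance = ~ feeding + landscape, detection = ~1),
  `L-FL`  = hds_fit(survey, abundance = ~ feeding + landscape,
                    detection = ~landscape)
)
hds_select(fits)$table
#>   model npar  logLik    AIC converged delta_AIC
#> 1 L-FL    12  -5884. 11792. TRUE             0
#> 2 FL       8  -6067. 12151. TRUE           358.
#> 3 L        7 -11450. 22914. TRUE         11121.
#> 4 null     3 -13632. 27269. TRUE         15477.
```

The feeding + landscape abundance model with landscape-dependent
detection wins decisively, and its feeding coefficient (0.0230 ±
0.0002) recovers the generator's truth (0.023). `predict_density()`
then maps expected birds/ha cell by cell and `total_abundance()` sums
the island total.

```r
samples <- gen_samples(150, seed = 103)
sim <- simulate_genotypes(samples, truth_config(n_loci = 500), seed = 104)
d2  <- genotypic_distance(sim$genotypes)
cg  <- genetic_correlogram(d2, cbind(samples$x, samples$y), seed = 105)
cg
#> <correlogram> 150 individuals, 15 classes of 2000 m
#>   zero-intercept 3220 m; envelope (U) intercept 3186 m
```

The generator's default field range is calibrated so the correlogram
enters its permutation envelope near 3 km — the genetic patch size.
With `autoplot(cg)` you get the r(h) curve, envelope and intercept;
`dresd()` maps the isolation-by-distance residual surface with
significance and power masks, and `covariate_correlation()` relates it
to the landscape.

All result objects have `tidy()`/`glance()` methods (coefficients,
per-class or per-cell tibbles) and `autoplot()` methods (rasters,
correlograms, density and resistance surfaces, PCA).

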