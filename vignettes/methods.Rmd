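---
title: "Models and methods in pigeonscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pigeonscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pigeonscape` couples two inferential machines that are usually run
separately — hierarchical distance sampling for abundance, and
individual-based landscape genetics for dispersal — behind one
synthetic-data generator with known ground truth. This vignette states
the models, the defaults and why they are what they are, the numerical
choices, and what the package's passing tests do and do not demonstrate
about real data.

## The study frame

All analyses live on a planar lattice (`grid_spec()`), by default 25
rows x 50 columns of 1 km cells — an island roughly 50 km east-west and
25 km north-south. Coordinates are planar metres; for data recorded in
degrees, `project_lonlat()` applies an equirectangular projection about
a reference point. Over a study area tens of kilometres across at low
latitude the projection distortion is far below the 2 km width of a
genetic distance class, so geographic distances are taken as Euclidean
in this plane. Row 1 is the northernmost row and cells are half-open
squares, so every point belongs to exactly one cell; points on the
outer boundary are clamped inward.

## Hierarchical distance sampling

A point-transect survey records, at each of `n_sites` points, the
radial distance and size of every detected bird cluster out to a
truncation radius B (default 100 m). The joint model is:

* abundance: clusters per hectare at site *i*,
  `log lambda_i = x_i' beta`, with covariates drawn from
  {intercept, feeding intensity F, landscape class L, population
  density P, road density R};
* detection: hazard-rate `g(r) = 1 - exp(-(r/sigma)^-b)` with
  `log sigma_i = w_i' alpha` (intercept or landscape) and a single
  shape `b` shared across landscapes — the smallest detection model
  consistent with landscape-dependent detectability. The hazard-rate
  family is used because its shoulder (g stays near 1 at small r)
  matches how observers detect conspicuous birds near the point.

Distances are binned into annuli (default 10 equal-width bins to B;
the bin scheme is a reported argument of `hds_fit()`). With
`pi_j(sigma, b) = (2/B^2) integral_{r_{j-1}}^{r_j} g(r) r dr`, the
expected count in bin j at site i is
`mu_ij = lambda_i (pi B^2 / 10^4) pi_ij` and the Poisson-per-bin
log-likelihood `sum y_ij log mu_ij - mu_ij` is maximized. This equals
the multinomial-Poisson mixture likelihood up to a data-only constant
(a unit test checks the identity on a worked instance). The annulus
integrals use fixed-order Gauss-Legendre quadrature inside the
optimizer (the integrand is smooth; 31 nodes agree with adaptive
quadrature to ~1e-10) and adaptive quadrature in the exported
`cell_probs()`.

Optimization is BFGS with an analytic gradient. The likelihood has a
known ridge — sigma and the abundance intercept trade off — and
finite-difference gradients stall on it; the analytic score makes
recovery reliable and fast. Starting values: the abundance intercept
from the mean observed count at 50% assumed detectability, the
detection intercept at log(B/2), other coefficients 0, and log b =
log 3. The covariance of the estimates is the inverse observed
information (finite differences of the analytic gradient at the
optimum). Non-convergence flags the fit and sets AIC to infinity;
`hds_select()` ranks converged fits by AIC with ties going to the
smaller model.

Prediction (`predict_density()`) applies only the abundance part per
cell and multiplies by the mean observed cluster size, since clusters
are the counting unit in the field; cluster sizes are
landscape-independent in the generator's default because the
cluster-size homogeneity test (Kruskal-Wallis in
`cluster_size_summary()`) is part of the workflow. Bare-ground cells
are never fitted or predicted (no surveys take place there), and
landscape classes absent from the fitted data are masked with a
warning rather than extrapolated. `total_abundance()` sums density
times cell area and reports a normal-approximation interval from
delta-method standard errors aggregated under cell independence; the
independence assumption is stated rather than hidden because
covariance between cell predictions sharing coefficients is otherwise
substantial.

## The synthetic-data generator

The generator defines the conditions every downstream test runs under.

* `gen_covariates()` draws the landscape raster as level sets of a
  smoothed Gaussian field so classes form contiguous patches in exact
  user-set proportions (largest-remainder rounding; the default gives
  bare ground 3.28% — 41 of 1,250 cells on the default grid — and
  splits the rest evenly). F, P and R are smoothed lognormal fields;
  feeding intensity has mean 20 incidents per cell and is winsorized
  at 8x its mean because it enters the abundance model through
  `exp(beta_F F)` — an unbounded lognormal tail would occasionally
  produce physically absurd cell densities.
* `simulate_surveys()` places sites uniformly within surveyable
  classes (never bare ground; dense trees down-weighted by 0.5 by
  default, reflecting how forested cells are under-sampled in
  practice), draws cluster counts Poisson from the abundance model,
  positions clusters with the triangular radial density `2r/B^2`,
  thins them by the hazard-rate curve, and sizes them as
  `1 + Poisson(s_bar - 1)` with `s_bar = 3.73`.
* The default abundance truth is `log lambda = 0.437 + 0.023 F + L`
  with landscape offsets HR 2.544, LR 1.421, ID 1.586, OV 1.255. No
  dense-tree coefficient accompanies these values, so the package sets
  `beta_DT = -2.5`, which puts dense-tree density at roughly 0.5
  birds/ha after the cluster-size multiplier — consistent with a
  landscape where the species is essentially absent. Detection scales
  default to 40-65 m by landscape with shape b = 3. Note that with a
  feeding field of mean 20 these coefficients imply a much denser
  island than most real surveys report; the generator's purpose is
  parameter recovery under a stated truth, not calibration of absolute
  densities.
* `simulate_genotypes()` draws, per locus, a latent Gaussian field
  with correlation `exp(-d^2 / (2 rho^2))` and marginal SD tau
  (default 1) at the individuals' coordinates, converts it to a local
  allele frequency by the logistic function, and samples genotypes
  Binomial(2, p). This gives isolation-by-distance structure whose
  patch size grows with rho, at a fraction of the cost of coalescent
  simulation and with direct control of the quantity under test. The
  rho-to-patch-size mapping was calibrated once by simulation (the
  table ships in
  `inst/extdata/patch_size_calibration_synthetic.csv`, a synthetic
  calibration artifact, not field data); the default rho = 1050 m
  yields a correlogram envelope intercept of ~3 km for 150 individuals
  on the default plane. Barriers are polygons; individuals are split
  by the side of the polygon's principal axis they fall on, and a
  stated fraction of loci draw independent fields per side. Kin
  injection appends Mendelian offspring of a sampled parent and an
  unsampled mate drawn from the sample allele frequencies, so each
  injection creates exactly one related pair.

What the generator does **not** emulate: real SNP ascertainment (its
allele frequencies centre on 0.5, so absolute heterozygosity is much
higher than typical ddRAD panels report — comparisons of He/Ho/F_IS
against field values are out of reach of these simulations),
linkage blocks (loci are exchangeable draws, so LD pruning is tested
on duplicated/correlated columns rather than genomic block structure),
demographic history (no bottlenecks or expansions), and observer
effects beyond distance (no availability or double-counting). Passing
recovery tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to every field artifact.

## Population-genetic statistics

`diversity()` reports per-locus He = 2p(1-p), observed heterozygote
fraction Ho, and F_IS = 1 - Ho/He for polymorphic loci. Because the
two conventions disagree slightly in practice, the summary reports the
inbreeding coefficient both as the mean of per-locus values and as the
ratio-of-means `1 - mean(Ho)/mean(He)`.

`relatedness_ml()` estimates, per pair, the probabilities (k0, k1, k2)
of sharing 0/1/2 alleles identical by descent under the no-inbreeding
model, maximizing `sum_l log(k0 P0 + k1 P1 + k2 P2)` over the
probability simplex with genotype-pair probabilities from
Hardy-Weinberg at the sample (or supplied) allele frequencies;
relatedness is r = k1/2 + k2. The maximization is a projected Newton
iteration on the two free coordinates (compiled code), with active-set
reduction — constraints at their bound with an outward gradient are
dropped from the Newton system, since the common optima (unrelated
pairs at k = (1,0,0), parent-offspring at (0,1,0)) sit on the simplex
boundary where naive projected steps crawl. A brute-force simplex grid
search serves as the independent oracle in the tests. Allele
frequencies include the pair itself (a small, documented bias), and
the estimator assumes one panmictic gene pool: under strong spatial
structure it reads shared patch membership as kinship, which is why
the kin-detection scenario in the tests uses an unstructured
background. Precision matters for the 10% kin threshold: at a few
hundred loci the sampling noise of r-hat for unrelated pairs spans the
threshold across thousands of pairs, so kin bookkeeping is exercised
at the several-thousand-locus scale typical of reduced-representation
SNP panels.

`genotypic_distance()` is the codominant squared distance for
biallelic loci — per locus 0/1/4 for identical/het-hom/opposite-hom
pairs, i.e. the squared allele-count difference — summed over loci.
`gen_pca()` centres on twice the allele frequency, scales by the
binomial SD by default, and eigendecomposes via SVD.

## Spatial autocorrelation

The squared-distance matrix is Gower double-centred
(`c_ij = -1/2 (d2_ij - m_i - m_j + m)`), and the class coefficient is
`r(h) = sum_{pairs in h} c_ij / sum_{pairs in h} (c_ii + c_jj)/2` over
even distance classes (default 15 x 2 km, upper-inclusive bins;
co-located pairs join the first class). A naive double-loop oracle
guards the vectorized implementation to 1e-12.

The null model permutes the assignment of coordinates to individuals,
leaving the genetic matrix intact; 999 permutations give the 95%
envelope and one-tailed p-values, and 999 within-class pair bootstraps
give confidence intervals. Note the permutation null of r(h) is
centred at -1/(n-1), not zero — the standard randomization expectation
for autocorrelation coefficients — and the tests assert exactly that.
The heterogeneity test standardizes each class against its permutation
distribution, `t2(h) = (r - mean)^2 / var`, sums into the global
omega, and computes add-one permutation p-values, so `p >= 1/(n+1)`
always.

Patch-size intercepts are found by scanning classes in order and
linearly interpolating between class midpoints at the first
down-crossing — of zero for the classical intercept, and of the
envelope's upper bound U for the patch size proper. If the curve
starts below the target the intercept is undefined (`NA`) rather than
zero: a curve already inside its null at the first class carries no
patch-size signal. `sex_stratified()` runs male/female/all
correlograms (unknown-sex individuals excluded from sexed strata) and
calls dispersal sex-biased when the bootstrap 95% intervals of the
male and female U-intercepts fail to overlap — a deliberately
conservative criterion that favours "no bias" under uncertainty.

## Isolation-by-distance residual mapping

`ibd_fit()` regresses the pairwise squared genotypic distance on
geographic distance by ordinary least squares over all unordered pairs
(linear distance by default; a log option exists because IBD linearity
over 50 km is an assumption, not a finding). Each pair's residual sits
at the arithmetic midpoint of the two individuals. The surface
(`interpolate_surface()`) is an inverse-distance-weighted mean (weight
`1/(d + cell_size/10)`; the offset keeps weights finite at co-located
midpoints) of residuals within a moving window (default radius 3,000
m), with cells below `min_pairs = 5` midpoints masked. The exact
kernel is a documented package choice, recorded in the output, since
the underlying method family does not fix one.

Significance (`dresd()`) permutes residual values across the fixed
midpoint geometry — preserving the spatial sampling design, which is
the null that barrier/corridor claims require — and computes two-tailed
per-cell p-values with the add-one rule, masked at alpha = 0.05. Power
resamples individuals with replacement (default 250 bootstraps),
rebuilds pairs, regression and surface (duplicate-individual
self-pairs are dropped; degenerate resamples redrawn), and reports the
per-cell sign-agreement fraction, with "sufficient power" at 0.95.
Both thresholds are package choices, stated in the object.
`covariate_correlation()` then reports Pearson correlations (landscape
expanded to per-class indicators) over all cells and over significant
cells; its p-values carry the caveat that spatial autocorrelation
among cells inflates them — no spatial correction is applied, matching
how these correlations are usually presented.

One behaviour worth knowing: under genuine island-wide
isolation-by-distance structure, many cells deviate from the
exchangeable-residual null, so the significance mask is not specific
to discrete barriers — it flags all spatially coherent residual
structure. The planted-barrier recovery test therefore uses a
long-range genetic field (rho = 25 km) in which the barrier is the
dominant violation; with the default short-range field the mask is
diffuse, which is a property of the method's null, not a bug.

## Problem sizes in the tests

The suite favours scales that demonstrate each property cleanly:
correlograms at 60-150 individuals x 200-500 loci; distance-sampling
recovery at 2,000 sites with 10 replicates and AIC selection at 600
sites x 50 replicates; kin bookkeeping at 144 individuals x ~7,000
loci; barrier recovery at 150 individuals x 300 loci over 10 seeds;
randomization calibrations at 199 iterations. The acceptance script
averages the patch-size recovery over 10 replicate simulations of 150
individuals x 500 loci with the full 999 permutations.

## Known limitations

* The generator's allele-frequency fields produce near-0.5 frequencies
  and coincident zero/envelope intercepts; real data typically show a
  zero-intercept well beyond the envelope intercept.
* The relatedness model assumes Hardy-Weinberg at known frequencies and
  no inbreeding; under strong spatial structure r-hat conflates patch
  sharing with kinship.
* The total-abundance interval ignores covariance between cell
  predictions and so understates uncertainty relative to a full
  propagation of the coefficient covariance.
* DResD-style inference is descriptive: the residual permutation null
  tests exchangeability, not a mechanistic dispersal model, and IDW
  interpolation has no uncertainty of its own.
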