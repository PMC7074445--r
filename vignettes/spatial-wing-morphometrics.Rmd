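---
title: "Spatially explicit wing morphometrics: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially explicit wing morphometrics: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wingcline detects spatial population structure from landmark-based wing
shape and from haploid SNP genotypes, and quantifies how well the two marker
systems agree. This vignette explains the statistical machinery, the
decisions behind every tunable default, what the synthetic generator does
and does not emulate, and the package's known limits.

## From pixels to shape

A wing is digitized as 19 homologous landmarks (vein junctions) in image
coordinates. Generalized Procrustes analysis (GPA) strips everything that is
not shape:

1. each configuration is centred and scaled to unit *centroid size* (the
   root of summed squared landmark distances from their centroid);
2. the consensus is initialized at the first shape;
3. each configuration is rotated onto the consensus by the closed-form
   (SVD) proper rotation — reflections are suppressed because all wings are
   right forewings;
4. the consensus is recomputed as the per-landmark mean, rescaled to unit
   size; steps 3–4 repeat until the consensus moves less than `tol`
   (RMS landmark displacement).

Defaults `tol = 1e-10`, `max_iter = 100` make convergence effectively exact
on wing data, where shape variation is tiny (site-level Procrustes
distances of order 1e-2 or less); widely dispersed artificial shapes can
need more iterations, so `gpa()` reports `iterations` and `converged`
rather than failing silently. Wings with any missing landmark are removed
before GPA (`filter_missing()`), exactly as a digitizing pipeline would do —
a missing vein junction cannot be superimposed.

Distances between shapes are *partial Procrustes distances*: the residual
root-sum-of-squares between two centred, unit-size, optimally rotated
configurations. We deliberately do not project to tangent space before
averaging or computing covariances: at the observed scale of variation the
difference is far below every tolerance used here, and skipping the
projection keeps colony and site means interpretable as plain landmark
averages.

Colony mean shapes are computed from one joint superimposition of the whole
caste dataset, then averaged per colony — not from per-colony GPAs — so all
colonies live in a common shape space.

## Ordination and site-level distances

Canonical variate analysis (CVA) maximises between-site relative to pooled
within-site variance of the flattened coordinates. Procrustes coordinates
are rank deficient (translation, scale and rotation remove 4 of the 38
dimensions), so the variables are first projected onto leading principal
components — by default enough to explain 99.9% of variance — before the
whitened between-group eigenproblem is solved. A singular pooled
within-group covariance after projection is reported as an error suggesting
a smaller `n_pca_keep` rather than being silently regularized.

Site-level differentiation is summarised by pairwise partial Procrustes
distances between site mean shapes, computed directly between the means
(equivalent to the group-mean shape distances that morphometrics software
reports alongside CVA output).

## The spatial analyses

**Connectivity.** Colonies, each at its own geographic coordinates, are the
analysis unit. The connection network links every colony to its `k = 5`
nearest neighbours by great-circle distance, symmetrizes the adjacency, and
row-normalizes. Five neighbours is a deliberately sparse default for
samples of hundreds of colonies clustered in sites: it keeps the network
local enough to resolve a cline while remaining connected under the
apiary-scale clustering of the design; it is exposed everywhere as `k`.
Neighbour ties are resolved by node index, with a warning when duplicate
coordinates make the choice arbitrary.

**sPCA.** Spatial PCA eigen-decomposes
`H = Xc'(L + L')Xc / (2n)` with `Xc` the column-centred feature matrix and
`L` the row-normalized weights. Each axis's eigenvalue is exactly the
product of the variance of its scores (population convention, 1/n) and
their Moran's I — positive eigenvalues are *global* axes (neighbours more
similar than random: clines, patches), negative ones *local* (neighbours
contrasting). The identity is asserted in the test suite to 1e-8 on every
axis.

**Morphometric input features.** The sPCA input for wings is the vector of
Euclidean distances between *proximal landmark pairs* — pairs adjacent
along the wing venation — computed on aligned (unit-size) colony means, so
features capture shape, not size. The venation adjacency is a configuration
file (`inst/extdata/proximal_pairs.csv`, 26 pairs), not a constant baked
into code: the appropriate pair set depends on the landmark scheme, and any
`i,j` list can be supplied. Features are centred (not standardized) inside
the sPCA; all distances share units, so variance weighting by feature is
meaningful and standardization is left to the caller.

**Structure tests.** The Monte-Carlo max(t) test asks whether the features
are distributed at random on the network. For each Moran eigenvector of the
network — the orthonormal spatial patterns of the doubly centred symmetric
weight operator, each with Moran's I equal to `n*lambda/sum(W)` — the mean
squared correlation (R²) with the feature columns is computed; the profile
is smoothed by a 3-point moving average over eigenvalue-adjacent
eigenvectors (the established window for this statistic; configurable), and
max(t) is the maximum over positive-I eigenvectors (global test) or
negative-I ones (local test). The null distribution jointly permutes the
feature rows; the p-value is `(1 + b)/(1 + B)`, so `B = 10000` permutations
make 1e-4 the attainable threshold. A seed is a required argument: no
permutation result in this package is irreproducible. `kind = "both"`
computes the global and local statistics from one permutation stream —
each keeps its own observed value, null distribution, and p-value.

**Interpolation.** First-global-score surfaces use inverse-distance-squared
weighting on a regular latitude/longitude grid, exact at sample locations
and masked outside the samples' convex hull; no variogram model is implied.

## Haploid F_ST

Drones are haploid, so F_ST uses a Hudson-type estimator on haploid counts:
per locus, numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
denominator `p1(1-p2) + p2(1-p1)`, combined across loci as a ratio of
averages (robust when per-locus denominators are small). This is the
least-assumption choice for haploid samples: no within-population
heterozygosity model, no variance components requiring diploidy. Missing
calls are excluded locus-wise; estimates are clamped to [0, 1] with the raw
value retained as an attribute.

## Concordance

Cross-caste and cross-marker agreement uses the Pearson correlation of
first global sPCA scores matched by colony. sPCA axes are sign-arbitrary,
so the report carries the signed r, the sign-aligned |r|, and whether a
flip was applied. Distance-matrix agreement (shape distances vs F_ST) is a
Pearson correlation over lower-triangle entries with the conventional
t-based p-value — and, because those entries are not independent, a Mantel
permutation p-value alongside it by default. Both are printed; the Mantel p
is the defensible one.

## The synthetic generator

No public archive holds the original wing coordinates or genotypes, so the
package ships a generator whose defaults encode the study design it stands
in for: 23 sites on three north–south transects (8 Atlantic, 9 Central, 6
Mediterranean), 10 apiaries per site, 3 colonies per apiary, 5 wings per
colony per caste, 19 landmarks, 383 haploid biallelic loci. A latent cline
value `q` per colony — the logistic of the standardized projection of its
coordinates onto a 45° (northeast–southwest) bearing — drives both markers:

- wing shape: template + `q * beta * d` + colony effect + wing effect +
  digitizing noise, rendered into image units by a random similarity
  transform per wing; `d` is a smooth deformation displacing distal
  landmarks relative to proximal ones, with all similarity-transform
  components projected out so the signal survives superimposition;
- genotypes: per-locus Bernoulli with log-odds `alpha_l + gamma_l (q - 1/2)`,
  slopes of random sign and magnitude around `gamma`.

Noise defaults (`colony_sd = 0.0025`, `wing_sd = 0.005`,
`digitize_sd = 0.002`, all in units of the unit-size template) put
colony-level scatter well below wing-level scatter, as replicate-wing
designs show. The clinal effect sizes (`beta = 0.08`, `gamma = 4`) are set
so the cline dominates colony noise — the regime the real data occupies,
where global structure is unambiguous (p below the attainable threshold)
and cross-marker score correlations are around 0.9. This makes synthetic
site-level shape distances a few-fold larger than the real study's
0.0037–0.0116 range: the generator reproduces the qualitative pattern
(global structure present, local structure absent, high concordance), not
the paper-scale effect magnitudes, which would require the undeposited
data to calibrate.

Per-landmark missing rates are caste-specific and anchored to the study's
reported elimination counts: about 5.9% of drone wings but only 0.4% of
worker wings lack at least one landmark, giving per-landmark rates of
0.003 (drones) and 0.0002 (workers) under independence. Haploidy exposing
deleterious alleles is the biological reading of that asymmetry.

What the generator does *not* emulate: linkage disequilibrium between loci,
coalescent genealogies, selection, allometry, measurement error correlated
across landmarks, beekeeper-mediated colony movement, or anisotropic
digitizing noise. Passing tests on synthetic data therefore demonstrate
that the pipeline recovers a cline it is built to contain — not that real
Iberian data would show one.

## Numerical choices and degenerate inputs

- GPA: consensus initialized at the first shape; order invariance of the
  fixed point is verified up to an overall rotation.
- Rank-deficient rotation problems (collinear landmark configurations) are
  flagged; the smallest-angle solution is returned.
- Degenerate shapes (all landmarks coincident) raise errors rather than
  returning NaN.
- Zero-variance feature columns are dropped from the sPCA with a warning;
  constant vectors are rejected by Moran's I.
- The Moran eigenbasis is built on an explicit orthonormal complement of
  the constant vector, so orthogonality to the intercept is exact, not
  approximate.
- Permutation p-values can never be zero by construction.

## Problem sizes used in the shipped checks

The test suite exercises the full default design (690 colonies per caste,
3,450 wings, 383 loci) for single analyses, 100 replicates at that scale
for the power/recovery checks (499 permutations each), and 500 replicates
of a 100-node noise design (199 permutations) for the type-I error of the
global test. The acceptance script runs one full-design analysis per caste
with 10,000 permutations, mirroring the analysis protocol end to end.

## Known limitations

- Great-circle KNN treats the sampling domain as isotropic; coastline or
  barrier effects are not modelled.
- CVA assumes equal within-group covariances; no robust or regularized
  variant is provided.
- The Mantel test uses simple (not partial) permutations.
- TPS parsing covers the `LM=`/`IMAGE=`/`ID=`/`SCALE=` dialect; curves and
  outlines (`CURVES=`) are out of scope.
- Site-level sPCA (one node per site) is available by passing site-level
  features and coordinates, but the colony-level analysis is the default
  and the tested path.
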