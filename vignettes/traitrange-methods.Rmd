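---
title: "Trait variability and range size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait variability and range size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitrange)
```

## The scientific question

Why do closely related tree species differ in range size by orders of
magnitude?  One long-standing hypothesis holds that species with greater
inherent variability in functional traits tolerate a wider spread of
environments and therefore come to occupy larger ranges.  `traitrange`
implements a regional-scale test of that idea built around congeneric pairs:
each pair couples one narrow endemic with one widespread species of the same
genus, sampled in the same local landscape, so that phylogeny and regional
environment are controlled and any systematic difference in *locally
expressed* trait variability can be attributed to the species themselves.

The pipeline has five stages, each usable on its own:

1. **Range size** — occurrence records are cleaned and each species' extent
   of occurrence (EOO) is the area of a Delaunay alpha-shape around the
   retained points under an equal-area projection.
2. **Trait variability** — per species, sample-size-corrected coefficients
   of variation (CV) of eight traits, and functional dispersion (FDis) in
   principal-component space.
3. **Variance decomposition** — nested random-effects partition of each
   trait's log-scale variance over genus, species, tree, and leaf levels.
4. **Environment** — a mesoclimate ordination score, crown-light index and
   slope per tree; environmental CVs per species; and an optional
   residualization of trait values against these covariates.
5. **Inference** — paired congeneric tests of CV/FDis differences
   (mixed-model intercept with a genus random effect, likelihood-ratio
   tests), prediction models `log10(EOO) ~ CV`, and Mantel tests of trait
   distance against geographic distance.

## Trait variability statistics

**Coefficient of variation.**  `cv()` is the sample standard deviation
(n − 1 denominator) over the mean.  Because species differ in how many
trees could be sampled (six to sixteen in the motivating design), raw CVs
carry a sample-size-dependent downward bias; `corrected_cv()` multiplies by
the normal-theory factor

\[ \mathrm{CV}^\* = \mathrm{CV}\left(1 + \frac{1}{4n}\right), \]

which removes most of the bias at n = 10 (verified by simulation in the
test suite: the corrected estimator's absolute bias is roughly 25 times
smaller than the raw one at a true CV of 0.2).  The factor is isolated in
one internal function so an alternative correction can be swapped in.  By
default CVs are computed on **tree-level values** — leaf-level traits (leaf
area, thickness, specific leaf area, dry matter content) are averaged over
the five leaves of each tree first — because within-tree variation is
accounted for separately by the variance decomposition.  `level = "leaf"`
switches to raw leaf values.

**Functional dispersion.**  The six non-derived traits (LA, LT, SLA, N, P,
WSG; LDMC and N:P are arithmetic combinations of others and are excluded)
are z-scored and rotated by PCA.  `trait_pca()` keeps `min(5, rank)`
components — five components, not a variance threshold — with a
deterministic sign convention (largest-magnitude loading positive).  FDis
per species is the mean Euclidean distance of its individuals to their own
centroid in that score space; it is translation- and rotation-invariant,
zero for identical individuals, and d/2 for two individuals a distance d
apart.  Species represented by a single tree get FDis 0 with a warning
rather than being dropped.

**Variance decomposition.**  `variance_decomposition()` fits, on
log-transformed values (natural log; proportions are base-invariant),

\[ y_{gstl} = \mu + a_g + b_{s(g)} + c_{t(s)} + \varepsilon_{l(t)} \]

by REML (`lme4`), with the residual level being the leaf for leaf-level
traits and the tree for tree-level traits (WSG, N, P, N:P), and reports the
variance components as proportions of their sum.  For balanced designs the
REML solution agrees with the method-of-moments expected-mean-squares
estimator to well under 1% (tested against an independent oracle).  With a
realistic number of genera the genus-level proportion is the noisiest
quantity: on a 20-genus design with half the variance at genus level its
sampling SD is about 0.06, so recovery checks average several replicate
datasets rather than trusting a single draw.

## Range size from occurrence records

**Cleaning.**  Three rules, in order, with removal counts recorded:

- *(a) distance outliers* — a record is removed when its nearest-neighbour
  distance is at least twice (configurable) the mean pairwise distance
  among all records **and** its locality metadata is suspicious (e.g.
  plantings in parks or gardens).  The conjunction is the default
  (`mode = "strict"`); `"permissive"` uses OR.
- *(b) grid deduplication* — at most one record per 1 × 1 km cell, grid
  anchored at the projection origin, lowest record id kept (deterministic).
- *(c) missing locality* — records without locality detail are dropped.

The full pass is idempotent on the generator's data and that property is
tested; in principle a second pass can flag new points (removals change the
mean distance), which is why the pass is applied once, in a fixed order.

**Projection.**  Geographic records are projected with a spherical Lambert
azimuthal equal-area projection centred on each species' own occurrence
centroid, which keeps area distortion below the percent level for regional
extents (verified against a geodesic-area oracle for a 1° quadrilateral).
Planar (synthetic) input passes through untouched.

**Alpha-shape EOO.**  The alpha-hull is operationalized as the union of
Delaunay triangles whose circumradius is at most alpha — a polygon, which
is what area computation and land-mask intersection need.  The
triangulation is an in-package Bowyer–Watson implementation validated in
the tests by the empty-circumcircle property and by exact agreement with
the convex hull at alpha = ∞.  `select_alpha()` walks an ascending
candidate grid and returns the smallest alpha whose shape is a valid,
non-degenerate (multi)polygon containing every point (a point is contained
exactly when it is a vertex of a retained triangle), falling back to the
convex hull with a warning when no candidate qualifies.

The candidate grid is configuration, not a constant, because the motivating
analysis' alpha = 8 is tied to its source coordinate units.  The default
grid is geometric, `diam/4` to `2·diam` in powers of two, where `diam` is
the cloud diameter.  That floor is a measured compromise: the
smallest-covering alpha-shape *always* underestimates area on contiguous
clouds (boundary slivers along hull edges have circumradii far larger than
the diameter, so some trimming happens at any practical alpha; even the
convex hull of 1000 uniform points in a convex polygon is about 1.6% small).
With the `diam/4` floor the mean relative area error over a battery of
convex shapes at n = 1000 is about 4%, with extreme aspect ratios reaching
~6%; finer floors (diam/8 and below) push the mean toward 5–10%.  Users
fitting strongly disjunct ranges should pass an explicit grid with smaller
candidates and accept the extra boundary bias.

**Land masks.**  `eoo_area()` intersects the shape with an optional land
polygon by clipping each retained triangle (Sutherland–Hodgman), which
handles concave and disconnected shapes but requires the *land* polygon to
be convex.  A general polygon-clipping backend was out of scope; synthetic
validation runs without a mask.

## Environment and residualization

`climate_pc1()` z-scores six climate variables, takes the first principal
axis, and shifts the scores by the absolute overall minimum so the smallest
score is exactly zero.  The shift reproduces the motivating analysis
faithfully but deserves a caveat: the CV is not shift-invariant, so
environmental CVs computed from shifted scores depend on that convention.
They are comparable across species within one analysis, which is the only
use made of them.

`residualize_traits()` implements the two-threshold screen: per species and
trait, each covariate (climate score, light, slope) is tested in a
univariate OLS regression; covariates with p < 0.1 enter one joint model;
those with p < 0.05 there are retained; and the trait is replaced by the
final model's residuals plus the original mean, exactly preserving the
mean.  Traits with nothing retained are returned unchanged, species with
fewer than five trees are skipped with a warning, and aliased covariates
are dropped with a note.  Under a pure-noise environment about 14% of
species × trait combinations are still altered (1 − 0.95³ from the nesting
of the two thresholds) — the procedure is a screen, not a test, and the
null behaviour is asserted at that derived rate in the tests, not at zero.

## Inference

**Paired congeneric test.**  For a metric m, the per-pair difference
Δ = m(widespread) − m(endemic) is modelled as `Δ ~ 1 + (1 | genus)` by
REML; genera contributing two pairs share one random intercept.
Significance of the intercept comes from a likelihood-ratio test between
the ML fits with and without the fixed intercept.  When the genus variance
is estimated at zero — which is guaranteed-confounded when every genus
contributes a single pair — the model reduces to the classical one-sample
ML likelihood-ratio test, and the implementation falls back to that exact
reduction (flagged in the result).  The equality of the two routes is a
tested invariant, and the test's type-I error at α = 0.05 is calibrated to
[0.03, 0.08] over 1000 null simulations.

**Prediction model.**  `log10(EOO) ~ CV + (1 | genus)` (base 10 chosen for
interpretability of the response; the base only rescales the slope).  Two
significance summaries are reported side by side, because mixed-model
practice uses both: the LRT p-value, and an F statistic on containment
(between-within) denominator degrees of freedom
`n − n_fixed − (n_genera − 1)`, which is 34 − 2 − 13 = 19 for the
34-species / 14-genus design.

**Mantel tests.**  Pearson correlation of the upper triangles of a
geographic-distance and a trait-distance matrix, with a one-sided (greater)
permutation p-value `(1 + #{r* ≥ r}) / (1 + n_perm)` under joint
row/column permutation; `n_perm = "exact"` enumerates all n! permutations
(n ≤ 8) and is exactly invariant to relabelling.  Raw significance counts
are reported across the species × trait grid, as in the motivating
analysis; Holm adjustment is available to the user via `p.adjust` but is
deliberately not applied by default.

## The synthetic-data generator

Because the motivating study deposits no raw trait measurements and its
occurrence sets are living database queries, validation runs on synthetic
data with known ground truth.  `synthetic_config()` defaults encode the
study design itself: 14 genera contributing 17 endemic/widespread pairs
(three genera give two pairs each), 10 trees per species, 5 leaves per
tree, and 200 occurrence records per species with 2% planted outliers and
5% planted in-cell duplicates.

Traits are lognormal: `mean × exp(a_g + b_s + c_t (+ e_l))` with
independent normal effects on the log scale, matching the log
transformation used in the variance decomposition and guaranteeing
positivity.  Default log-scale variances (genus 0.04, species 0.02, tree
0.01, leaf 0.005) put most variation between genera and species and give
tree-level CVs near 0.10, the magnitude observed for conservative traits
such as wood density.  The tree-level CV is exactly
`sqrt(exp(sigma_tree^2) − 1)`, so per-species CV targets (used to inject
known endemic/widespread contrasts) are honoured by inversion,
`sigma^2 = log(1 + cv^2)`; for leaf-level traits the per-leaf noise rides
on top, so targets are exact only for tree-level traits and for tree means
as the leaf count grows.

Occurrences are uniform in a supplied polygon (rejection sampling).
Planted outliers sit evenly spaced on a circle at least six polygon
diameters out, and the radius is enlarged until every outlier's
nearest-neighbour distance provably exceeds twice the contaminated cloud's
mean pairwise distance — so the distance rule is guaranteed to see them and
cleaning has a deterministic expected outcome.  Planted duplicates are
jittered within 10 m of a parent point and clamped into the parent's 1-km
cell.  Environmental covariates are one latent climate factor with loading
0.912 on each of six standardized variables (first axis ≈ 86% of
variance), an integer light index 0–5, and a half-normal slope; optional
trait–environment couplings are added on the log scale so residualization
recovery is testable.

All draws descend from one master seed through fixed prime-multiple
offsets per stream (traits, per-species occurrences, environment), so any
stage is reproducible in isolation and a fixed configuration is
byte-identical across runs.

What the generator does **not** emulate: spatial autocorrelation of traits
within species (tree coordinates are not simulated, so in-pipeline Mantel
tests are exercised on constructed matrices), non-lognormal trait shapes,
measurement error distinct from leaf-level noise, and realistic coastline
land masks.  Passing tests therefore demonstrate correctness of the
machinery and calibration of the tests under the stated model, not that
real data meet those assumptions.

## Numerical choices and degenerate inputs

- Delaunay in-circle decisions use a relative tolerance of 1e-10;
  cocircular groups (grid data) are re-fanned deterministically, which can
  change diagonals but never areas.  Collinear point sets are rejected.
- Alpha-shape containment counts boundary points as inside; an empty shape
  (alpha below the smallest circumradius) is legal and has area 0.
- `paired_intercept_test` and `range_prediction_model` treat zero-residual
  and constant-response cases exactly (LRT statistic 0 or ∞) instead of
  relying on the optimizer; singular or failed mixed fits fall back to the
  documented OLS reductions and are flagged.
- Mean-preservation in `residualize_traits` is exact because OLS residuals
  sum to zero; the test asserts equality at machine precision.
- Problem sizes in the validation suite (n = 1000 occurrence clouds, 16
  replicate decompositions of a 20 × 4 × 10 × 5 design, 1000-simulation
  null calibrations, 500-seed Mantel uniformity) were chosen so each check
  pins its quantity with comfortable Monte-Carlo margin.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(synthetic = synthetic_config(seed = 1))
res <- run_pipeline(cfg)
res                      # recovery and significance summary
res$pair_stats           # per-pair EOO differences and ratios
res$paired_tests$FDis    # paired congeneric test of functional dispersion
res$prediction_models$FDis
```

Under the default null configuration (no injected CV contrast between
endemic and widespread species) the paired tests and prediction models are
expected to be non-significant at their nominal rate, and the recovered EOO
per species sits within a few percent of its generating polygon's area.

## Known limitations

- Land-mask intersection requires a convex mask.
- The smallest-covering alpha rule has a small negative area bias
  (documented above); EOO values are best interpreted comparatively.
- Genus-level variance proportions are inherently noisy with few genera.
- Environmental CVs depend on the non-shift-invariant score convention.
- The Mantel stage requires user-supplied distance matrices, as individual
  tree coordinates are outside the generator's scope.
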