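# traitrange

Does locally expressed intraspecific trait variability predict how large a
species' geographic range is?  `traitrange` implements a regional-scale test
of that hypothesis for trees, built around **congeneric pairs** of one
narrow endemic and one widespread species sampled in the same landscape —
a design that controls phylogeny and regional environment, so a systematic
variability difference between pair members can be read as a property of
the species rather than of their surroundings.

The package is aimed at macroecologists and functional-trait ecologists who
want the whole chain — occurrence cleaning, range geometry, variability
statistics, environmental adjustment, paired mixed-model inference — as
tested, composable R functions, together with a synthetic-data generator
with known ground truth for validating every stage.

## What it computes

**Range size.**  A species' extent of occurrence (EOO) is the area of a
Delaunay alpha-shape (the polygonal alpha-hull) around its cleaned
occurrence records under a Lambert azimuthal equal-area projection:

- cleaning rule (a): records whose nearest neighbour is at least twice the
  mean pairwise distance *and* whose locality metadata is suspicious;
- rule (b): duplicates within the same 1 × 1 km grid cell;
- rule (c): records without locality detail.

`select_alpha()` picks the smallest alpha from a candidate grid whose shape
is a valid polygon containing every point, with a convex-hull fallback.

**Variability.**  Per species: the sample-size-corrected coefficient of
variation CV·(1 + 1/(4n)) of each of eight traits (LA, LT, SLA, LDMC, WSG,
N, P, N:P), and functional dispersion (FDis) — the mean distance of a
species' trees to their centroid in the space of the first five principal
components of the six non-derived traits.  Nested variance decomposition
partitions each trait's log-scale variance over genus / species / tree /
leaf via REML random-effects models.

**Inference.**  Per metric m, pair differences Δ = m(widespread) −
m(endemic) are tested with `Δ ~ 1 + (1 | genus)` and a likelihood-ratio
test of the intercept; range prediction uses `log10(EOO) ~ m + (1 | genus)`
with both LRT p-values and F statistics on containment degrees of freedom
(19 for the 34-species / 14-genus design).  Mantel tests relate trait
distance to geographic distance, with exact enumeration available.  An
environmental back-up analysis residualizes traits against a climate
ordination score, crown light and slope (p < 0.1 screen, p < 0.05
retention) before recomputing everything.

## Worked example

The package ships the 34-species study table (17 congeneric pairs, printed
extents of occurrence in km²):

```r
library(traitrange)
tab <- study_species_table()
pair_range_stats(tab, sig_figs = 2)
#> 17 congeneric pairs
#>   EOO difference (widespread - endemic): min 27000, max 1.3e+07 km^2
#>   EOO ratio over within-genus combinations: min 7.5, max 220000
```

The smallest widespread-minus-endemic gap is 2.7·10⁴ km² (the *Unonopsis*
pair) and the tightest within-genus ratio is 7.5 (*Guatteria rostrata* vs
*G. chiriquiensis*): even the most similar pair differs by a factor of
seven in range size, which is what makes the binary endemic/widespread
classification meaningful.

A full synthetic run with the default (null) configuration — the study's
sampling design, no injected variability contrast:

```r
res <- run_pipeline(pipeline_config(synthetic = synthetic_config(seed = 1)))
res
#> Pipeline result: 34 species, 17 pairs
#>   EOO recovery: median |error| 10.19%
#>   paired congeneric tests: 0 of 18 with p < 0.05

res$paired_tests$FDis
#> Paired congeneric test (FDis), 17 pairs
#>   widespread - endemic intercept: -0.03426 (SE 0.0466)
#>   genus random-intercept variance: 0 (one-sample reduction)
#>   LRT chi^2(1) = 0.565, p = 0.4524
```

No paired test rejects — as it must not, since no contrast was injected —
and recovered EOOs track the generating polygons (the ~10% median error at
200 records per species drops below 5% at 1000 records).  Injecting a CV
gap via `species_cv_targets` turns the paired tests on: power against a
0.05 CV gap is already above 90% with 10 trees per species.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/traitrange.R` (`simulate`, `range`, `all` subcommands).

## Package layout

- `R/synthetic.R` — generator (design, traits, occurrences, environment)
- `R/geometry.R`, `R/range.R` — Delaunay/alpha-shape geometry, projection,
  cleaning, EOO, pair statistics
- `R/traits.R` — CV, corrected CV, PCA, FDis, variance decomposition
- `R/environment.R` — climate ordination, environmental CVs, residualization
- `R/inference.R` — paired tests, prediction models, Mantel tests
- `R/io.R`, `R/pipeline.R` — CSV/GeoJSON readers and writers, end-to-end
  driver with run manifest
- `vignettes/traitrange-methods.Rmd` — models, assumptions, parameter
  defaults, numerical choices, limitations
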