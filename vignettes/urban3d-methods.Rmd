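---
title: "Methods: 3D landscape pattern, LUR PM2.5 surfaces, and GWR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D landscape pattern, LUR PM2.5 surfaces, and GWR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urban3d)
```

`urban3d` studies how the three-dimensional pattern of urban built form
relates to fine particulate matter (PM2.5), through four coupled pieces:
land-function zoning, 3D landscape indices, a land-use regression (LUR)
PM2.5 surface, and geographically weighted regression (GWR) of zonal
PM2.5 on zone morphology. This vignette documents the models, the
numerical choices, the design of the synthetic city that drives all
tests, and the limits of what those tests demonstrate.

## Land-function zoning

A function zone is a limited area dominated by one land use. A candidate
polygon is classified from its land-use composition (area shares from
exact rectangle intersections): residential, commercial or educational
when that class occupies *strictly more than* 50% of the candidate,
industrial at strictly more than 40%. Thresholds are strict because the
rules say "more than". When several rules fire the largest share wins;
an exact tie is left unclassified — the method is meant for areas with a
distinct function, so ambiguity is resolved conservatively. Candidate
polygons are an input: zone delineation in practice is a manual,
plan-informed step, and the package does not attempt to automate it.

## Building heights, categories, and the six indices

Heights come from floor counts: 2.8 m per floor for civil buildings,
5.0 m for industrial plants. Volume is footprint area × height, i.e. the
top contour is identified with the footprint (buildings are prisms).

The eight built-form categories (bungalow … super-high-rise) are defined
by height intervals that *do not partition* the positive axis, because
they enumerate heights attainable under the two floor modules. For
totality, a height falling in an inter-bin gap (e.g. 15.0–19.6 m) is
assigned to the category with the nearest interval endpoint, ties going
to the lower category; 17.0 m is therefore "multistory"
(|17−15| < |19.6−17|). The bungalow lower bound (2.8 m) is inclusive.

Per sample area (zone) with buildings `i = 1..n`:

| index | formula | units |
|---|---|---|
| height density | `H̄ = Σ H_i / n` | m |
| volume density | `E_vol = Σ V_i / (Hmax · S)` | — |
| spatial dispersion | `L = sqrt((1/n) Σ (H_i − H̄)²) / H̄` | — |
| fluctuation | `LHR = Hmax − Hmin` | m |
| building diversity | `S_div = −Σ P_i ln P_i` | nats |
| building uniformity | `E_uni = 100 · S_div / ln m` | % |

Numerical choices worth stating:

* **Dispersion** is read as the coefficient of variation with the
  *population* (1/n) standard deviation — the common "landscape
  dispersion" reading, and it makes `L` invariant to rescaling all
  heights.
* **`P_i` are footprint-area shares** of the height categories (the
  area occupied by buildings of each type), not building counts.
* **`Smax = ln m`** uses the number of categories *present* in the
  sample (the maximum diversity attainable in that landscape); a
  single-category sample has `E_uni = 0` by convention. The global
  alternative `ln 8` is available via `smax_global = TRUE`.

## Land-use regression

Monthly mean PM2.5 at the 16 monitoring sites over 12 months (192
records) is regressed on:

* buffer predictors at radii 500, 1000, 1500, 2000, 3000, 4000, 5000 m —
  the enumerated list is used even though it is sometimes summarised as
  "six buffers": road densities MROAD/SROAD/TAL (m of road per m² of
  buffer) and land-use shares VEG (ecological incl. water), INDU, WAT,
  RAR, POP (residential share as a population proxy), named
  `<FAMILY><radius>`;
* monthly meteorology: PRS, PRS_Sea, WIN, TEM, RHU, PRE_1h.

Buffers are polygonal circles (128 vertices) clipped against the parcel
rectangles; shares use the polygonal circle's own area as denominator,
so symmetric configurations are exact (a half-split buffer gives exactly
0.5) and the discretisation bias cancels in the ratio. Land outside the
mapped extent contributes zero.

Fitting follows the classic two-stage screening-and-removal procedure:

1. **Screening.** Within each subcategory (one buffer family across its
   radii; meteorological variables are singletons) keep the member with
   the largest |Pearson r| against PM2.5. Rank the winners by |r| and,
   walking down the ranking, drop any variable with |pairwise r| > 0.6
   against an already-accepted one. Dropping the lower-ranked member of
   a collinear pair is our reading of the procedure; since acceptance is
   greedy from the top, this coincides with discarding the subcategories
   collinear with each accepted variable.
2. **Backward removal.** Fit OLS on the survivors; remove *all*
   variables with two-sided t-test p > 0.10 (90% confidence); refit
   until no removal occurs. The loop terminates in at most as many
   iterations as variables. Removal-only is implemented (the source
   procedure describes removal until convergence, not re-entry).
3. **Sign enforcement is off by default.** Each family has an a-priori
   direction (`assumed_signs()`), and `enforce_sign = TRUE` removes
   contradicting coefficients. The default is off because the reference
   final model itself retains a precipitation term with a positive
   coefficient against a negative a-priori sign — enforcement would
   delete a variable that the reference analysis kept.

Validation is a seeded 75/25 hold-out split: mean absolute error rate
`mean(|ŷ−y|/|y|)` (records with y = 0 skipped with a warning) and RMSE.

**Surface prediction** rasterises the parcel mosaic (cell-centre class,
default 100 m cells) on the buffer-padded extent and computes each
model term as a circular focal mean via FFT convolution; road layers use
rasterised road length. Meteorological terms are evaluated at
user-supplied values, default 0 — the annual mean of standardized
anomalies — so the default surface is the annual-mean field. Output is a
plain-text ASCII grid raster.

## Inference across zones

Zonal mean PM2.5 is the mean of raster cells whose centres fall in the
zone. Differences across the four zone types use one-way ANOVA (with a
single factor the Type III and sequential decompositions coincide, so
the table is computed via `lm`/`anova`) and Fisher's LSD post hoc
comparisons: pairwise mean differences with pooled standard error
`sqrt(MSW (1/n_I + 1/n_J))` and t-tests on the within-group degrees of
freedom, without multiplicity adjustment (that is the definition of
LSD). Index–PM2.5 associations are Pearson correlations with two-sided
t-based p-values.

## Geographically weighted regression

GWR fits, at every zone centroid, weighted least squares with Gaussian
kernel weights `w_ij = exp(−(d_ij/b)²)`. The paper-standard fit
statistics use the hat-matrix trace as the effective number of
parameters; AICc is `n log(RSS/n) + n log 2π + n(n+tr S)/(n−2−tr S)`.
Standardized residuals are internally studentized with
`σ̂² = RSS/(n − tr S)`. Design choices where the method is
conventionally open:

* **Kernel and bandwidth**: fixed Gaussian kernel with AICc-minimising
  bandwidth — the most common default. Selection scans a log-spaced
  grid from diameter/50 to twice the point-cloud diameter and refines
  the grid minimum by golden-section search; a non-unimodal profile
  falls back to the grid minimum with a warning. Selection is
  deterministic given the data.
* **Singular local designs** (all weight on collinear points) fall back
  to a small ridge with a warning rather than failing.
* **Residual diagnostics**: Moran's I with row-standardized
  inverse-distance weights, expectation −1/(n−1), and a seeded
  two-sided permutation p-value (999 permutations). A p-value above
  0.05 is read as spatially random residuals, hence a credible model.
  (The source material is internally inconsistent about this rule in
  one place; the package applies the p > 0.05 credibility reading.)
* **Predictor choice per zone type**: the index most correlated with
  zonal PM2.5, plus the strongest remaining index correlated with the
  first below 0.6 — mirroring the LUR screening logic at the zone
  level. The selection follows this algorithm, not any fixed pairing of
  index names.

## The synthetic city

No real monitoring, cadastral or 3D-building data are distributed with
the package, so all analyses run on a synthetic city whose statistical
structure matches the assumptions of the analysis chain. Two principles
shaped its design.

**One city, one geography.** The urban layout — land-use mosaic, zone
placement, road grid, monitoring network — is generated from a fixed
`layout_seed` and does *not* change with the simulation seed, which
drives only the measurement-level layers (building stock, meteorology,
PM2.5 noise). A study area has a single geography; holding it fixed
makes the screening behaviour of the LUR procedure a property of the
designed city rather than of per-seed sampling noise in 16-site
correlations. Changing `layout_seed` produces a different city.

**The layout realises the analysis assumptions.** The default city is a
24 km square (≈576 km², one site per 36 km², matching a ~35 km²-per-site
network density) with:

* a monocentric ecological gradient (bare core to green fringe) with
  block-scale forest-park patchiness, so ecological shares at different
  buffer radii are distinguishable rather than near-collinear;
* a river with a floodplain-agriculture corridor (water and arable land
  have their own spatial patterns, not mirrors of the green gradient);
* west-biased residential development (the population proxy is not a
  complement of greenery);
* a radial road grid, denser in the core (road variables collapse onto
  the urban gradient and are screened out by the 0.6 rule, echoing the
  common finding that traffic terms add nothing across a uniformly
  well-connected centre);
* 61 function zones (16 industrial, 14 educational, 18 residential, 13
  commercial) with per-type area ranges and means matching the study
  design, placed on a non-overlapping grid with a dominant-class share
  drawn above the classification threshold (a configurable fraction of
  candidates is generated "mixed", classifiable as nothing);
* zone-type floor-count distributions (industrial 1–3 plant floors;
  residential up to 33 civil floors; commercial and educational in
  between) so mean heights and diversity genuinely differ by type;
* a 16-site network of background stations near the fringe, urban-core
  stations, and stations at staggered distances from industrial
  facilities (inside the parcel to 550 m outside), giving the local
  industrial share real between-station variance.

Monthly meteorology is generated as standardized anomalies with an
*exact* in-sample correlation structure (Gram–Schmidt): the
precipitation and sea-level-pressure anomalies — the two drivers in the
PM2.5 generating equation — are orthogonal, while temperature and
humidity load 0.80/0.90 on precipitation and station pressure and wind
load 0.97/0.75 on sea-level pressure (a monsoon climate: hot-wet
summers, high-pressure windy winters). Each met decoy is therefore
strictly out-ranked by, and more than 0.6-correlated with, its anchor,
so screening removes it — while both true drivers stay identifiable.

PM2.5 is the linear combination
`41.308 − 5.921·VEG5000 + 40.316·PRE + −26.102·PRS_Sea + 4.088·INDU500`
plus Gaussian noise, by default 1% of the deterministic response SD. The
met columns are stored as anomalies scaled to SD 0.25 (`met_scale`):
with unit-variance anomalies those coefficient magnitudes would imply
monthly swings of ±100 µg/m³ and negative concentrations, whereas the
default keeps the panel in a realistic 15–70 µg/m³ range; `met_scale =
1` restores unit variance. Coefficient recovery is unaffected because
the truth equation applies to the stored columns.

With this design, the test suite verifies (20 simulation seeds, fixed
in the tests) that the full screen-and-remove pipeline retains all four
generating predictors and recovers every coefficient within 5 relative
percent in at least 18 of 20 replicates. Exact predictor-*count*
retention is intrinsically stochastic: each decoy family that survives
screening is retained spuriously with probability ≈ α = 0.10 under the
p > 0.10 removal rule, so the suite requires exactly-four retention in
at least half the replicates rather than always.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: measurement error in buffer predictors;
within-month temporal dynamics; non-rectangular geometry; spatially
correlated model error (the noise is iid, so LUR assumptions hold by
construction); terrain and street-canyon effects; and real cities'
messier collinearity, under which the screening procedure can behave
less cleanly than here.

## GWR testbed

`generate_gwr_testbed()` draws locations uniformly, two standard-normal
covariates, and a response whose local coefficients are linear fields:
one slope decreasing monotonically west→east, one increasing
south→north, with noise defaulting to 5% of the response SD. The tests
require the AICc-selected Gaussian GWR to recover the first slope field
with mean absolute error under 20% of its range at n = 200, and the
fitted local slope to correlate below −0.8 with easting.

## Problem sizes and tolerances in the test suite

The suite uses the default 192-record panel for recovery checks (20
seeds), n = 200 for the GWR testbed, n = 25 with 999 permutations × 50
seeds for Moran calibration, and 1000/200 simulations for ANOVA null
calibration and power; these sizes give stable Monte-Carlo estimates
while keeping the full suite around a minute. Exactness claims
(index formulas, constant-coefficient GWR, ANOVA decompositions) are
tested at 1e-8–1e-12; calibration bands ([0.03, 0.07] null rejection,
[0.01, 0.12] Moran rejection) reflect binomial noise at those
simulation counts.

## Known limitations

* Geometry is planar and rectangular throughout (parcels, zones,
  footprints); there is no CRS handling. This matches the Euclidean
  buffer workflow but excludes real cadastral shapes.
* The raster surface uses cell-centre class assignment and cell-centre
  buffer evaluation; sub-cell mixing is ignored at the default 100 m
  resolution.
* GWR per zone type runs on 13–18 locations, as in the study design it
  mirrors; local coefficient maps at such n are indicative, not
  inferential — the Moran check guards against gross residual
  structure, nothing more.
* The stepwise procedure inherits the classical caveats of
  significance-driven selection; it is implemented as specified, not as
  a recommendation.
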