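# urban3d

How does the three-dimensional form of a city — how tall, how crowded,
how varied its buildings are — shape the distribution of fine particulate
matter (PM2.5)? `urban3d` implements a complete, reproducible pipeline
for that question, aimed at urban landscape ecologists and exposure
modellers:

1. **Land-function zoning.** Urban land-function zones (residential,
   commercial, industrial, educational) are identified from parcel
   composition by area-dominance rules: residential/commercial/
   educational land must exceed 50% of a candidate polygon, industrial
   land 40%.
2. **3D landscape pattern indices.** Per zone, six indices of built
   form, computed from building heights `H_i` (floors × 2.8 m for civil
   buildings, × 5.0 m for industrial plants), volumes
   `V_i = footprint × H_i`, and eight height categories:
   - height density `H̄ = Σ H_i / n`
   - volume density `E_vol = Σ V_i / (Hmax · S)`
   - spatial dispersion `L = sd_pop(H) / H̄` (coefficient of variation)
   - fluctuation `LHR = Hmax − Hmin`
   - building diversity `S_div = −Σ P_i ln P_i` (Shannon entropy of
     footprint-area shares over height categories)
   - building uniformity `E_uni = 100 · S_div / ln m`
3. **Land-use regression (LUR).** PM2.5 at monitoring sites is
   regressed on buffer-extracted predictors (road densities and
   land-use shares at 500–5000 m radii) and meteorology, using the
   classic two-stage procedure: per-family correlation screening with a
   |r| > 0.6 collinearity prune, then backward removal of terms not
   significant at the 90% level until convergence. The fitted model is
   evaluated by 75/25 hold-out validation and projected to a raster
   PM2.5 surface.
4. **Inference and GWR.** Zonal mean PM2.5 is compared across zone
   types (one-way ANOVA + LSD post hoc), correlated with the 3D
   indices, and modelled per zone type by geographically weighted
   regression `y_i = β_0(u_i,v_i) + Σ_k β_k(u_i,v_i) x_ik + ε_i` with a
   Gaussian kernel, AICc bandwidth selection, and Moran's I permutation
   diagnostics on standardized residuals.

Because the original monitoring and cadastral data are not openly
deposited, the package ships a first-class **synthetic-city generator**:
a fixed urban layout (monocentric green gradient, river and floodplain,
west-biased residential development, radial road grid, 61 function
zones, a 16-site monitoring network) on which building stocks,
meteorology, and PM2.5 are simulated from a known generating equation.
Every downstream stage is therefore testable against stored ground
truth.

## Worked example

```r
library(urban3d)

cfg    <- city_config(seed = 1)        # 16 sites x 12 months, 61 zones
city   <- generate_city(cfg)

design   <- build_design(city$panel, city$site_predictors)
screened <- screen_variables(design, city$panel$PM25)
model    <- fit_lur(design, city$panel$PM25, screened$retained)
model
#> LUR model: 192 records, 4 retained predictor(s)
#> (Intercept)      PRE_1h     PRS_Sea     INDU500     VEG5000
#>     41.3241     40.3453    -26.1044      4.0861     -5.9730
#> R^2 = 0.9999  adj R^2 = 0.9999
```

The generating equation had intercept 41.308 and coefficients −5.921
(VEG5000, ecological share in a 5 km buffer), +40.316 (precipitation
anomaly), −26.102 (sea-level-pressure anomaly), +4.088 (INDU500,
industrial share in a 500 m buffer): the screening-plus-stepwise
procedure retained exactly those four predictors and recovered every
coefficient within 1%.

```r
zones <- identify_zones(city$parcels$parcels, city$parcels$candidates)
zone_summary(zones)
#>     zone_type  n  min_km2  max_km2 mean_km2
#> 1  commercial 13 0.320    0.461    0.378
#> 2 educational 14 0.417    2.362    1.200
#> 3  industrial 16 0.402    1.801    0.901
#> 4 residential 18 0.507    1.073    0.672

surf <- predict_surface(model, city$parcels, city$roads, res = 200)
surf
#> pm_raster: 120 rows x 120 cols, res 200 m, origin ( 0 , 0 )
#> values: min 36.92  mean 38.94  max 43.03
```

The annual-mean surface spans ~37–43 µg/m³, highest around industrial
zones and lowest over the green fringe. Mean building height separates
the four zone types sharply (one-way ANOVA on zonal `H̄`:
F = 1923, p < 2e-16), and a per-type GWR of zonal PM2.5 on two
collinearity-screened indices reports local coefficients, R², bandwidth
and a Moran's I residual check, e.g. for the industrial zones:

```r
#> GWR fit: 16 locations, 2 covariate(s), bandwidth 46307 m ( gaussian )
#> R^2 = 0.367  adj R^2 = 0.2624  ENP = 3.13  AICc = 45.14
#> Moran's I of std residuals = -0.1068  (expected -0.0667 , p = 0.506)
```

A Moran p-value above 0.05 indicates spatially random residuals, i.e. a
credible local model.

The whole chain — simulate → zones → indices → LUR → surface → zonal
statistics → GWR — runs as one call with a checksum manifest and
incremental resumption:

```r
run_pipeline(pipeline_config(city = cfg), out_dir = "results")
```

## Package layout

- `R/synthetic_city.R` — city configuration, layout, building stock,
  meteorology, monitoring panel, GWR testbed
- `R/zoning.R`, `R/landscape3d.R` — function-zone identification and 3D
  indices
- `R/lur.R` — buffer extraction, screening, stepwise fit, validation,
  surface prediction
- `R/gwr.R` — GWR, bandwidth selection, Moran's I
- `R/inferential_stats.R` — zonal means, ANOVA, LSD, correlations
- `R/pipeline.R`, `R/geojson.R`, `R/raster.R` — orchestration and
  plain-text GeoJSON / ASCII-grid I/O
- `vignettes/urban3d-methods.Rmd` — the methods vignette (model,
  assumptions, generator design, limitations)
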