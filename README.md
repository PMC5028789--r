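# bathytraits

Trait-based functional, size and taxonomic diversity of demersal fish
assemblages along depth gradients, from bottom-trawl survey data.

## The problem

Continental-slope fish communities change almost completely in species
composition between 300 m and 2,000 m, but species lists alone cannot say
whether the deep community does the same ecological *jobs* as the shallow
one. This package takes haul-level trawl records (who was caught, where,
how long the tow was, and each fish's measured length) and produces
station-level diversity metrics built on morphology and body size rather
than taxonomy, then smooths each metric against depth. It is written for
fish ecologists working with deep-water survey data and ships a synthetic
survey generator with known ground truth, so the whole pipeline is testable
without access to restricted survey databases.

## What it computes

For each station (hauls pooled within an ICES rectangle and 100 m of depth):

* **Functional richness (FRic)** — the convex-hull volume of the station's
  species in a trait space built from eight morphological traits via Gower
  dissimilarity and principal coordinates: `FRic = vol(conv{x_i})`,
  abundance-free.
* **Functional divergence (FDiv)** — with `g` the centroid of the hull
  vertices, `dG_i = ||x_i − g||`, `d̄` their unweighted mean, and biomass
  weights `w_i`: `FDiv = (Σw_i(dG_i − d̄) + d̄) / (Σw_i|dG_i − d̄| + d̄)`,
  in [0, 1].
* **Size diversity** — the similarity-sensitive diversity of order
  q = 1.1 over 10-cm body-size classes,
  `D = (Σ_i p_i ((Zp)_i)^{q−1})^{1/(1−q)}`, with `p` proportional biomass
  per hour per class and `Z_ij = e/(ln 2 · d_ij)` from midpoint distances.
* **Species richness** — mean species count over hauls of 120 ± 5 min.
* Abundance-weighted trait means/SDs, mean individual length,
  isotope-based feeding-guild assignment, guild biomass composition in
  200-m depth bands, and `mgcv` GAM depth trends (REML, cubic regression
  splines) with F, e.d.f., adjusted R² and p per metric.

The convex-hull volume/vertex computation (exact facet enumeration in up to
6 dimensions), the availability-weighted Gower coefficient, the principal
coordinates embedding, and the similarity-sensitive diversity are all
implemented in the package and validated against independent oracles in the
test suite.

## Worked example

```r
library(bathytraits)

cfg <- pipeline_config(seed = 1, out_dir = "run1")   # synthetic mode
out <- run_pipeline(cfg)
out$trend_summaries
#> # A tibble: 4 × 6
#>   metric         f_stat   edf    r2 p_value     n
#>   <chr>           <dbl> <dbl> <dbl>   <dbl> <int>
#> 1 fric_norm        70.7  7.79 0.885       0    80
#> 2 fdiv             41.3  8.71 0.823       0    80
#> 3 size_diversity   41.4  6.89 0.807       0    80
#> 4 richness         25.1  6.74 0.793       0    52
```

Each row summarises the GAM of one metric against station depth: `f_stat`
and `p_value` test the smooth term, `edf` is its effective flexibility
(≈1 would be a straight line), and `r2` the adjusted variance explained.
In this synthetic scenario the generator plants trait-extreme,
size-extreme species at mid-depth, so functional richness and size
diversity rise to a dome near 1,150 m — visible in the fitted curves:

```r
fric <- out$trends[[1]]
fric
#> <depth_trend> fric_norm ~ s(depth), n = 80
#>   F = 70.74, e.d.f. = 7.79, adj. R^2 = 0.885, p = 0
tidy(fric)$depth_m[which.max(tidy(fric)$fitted)]
#> [1] 1103.8
autoplot(fric)                     # fitted curve ± 2 SE over the stations
```

`run1/` receives the station table, per-station diversity table, trait
moments, guild composition, trend summaries and curves as CSV, plus a JSON
manifest of the configuration; identical config and seed give byte-identical
outputs. With `mode = "files"` the same pipeline runs on your own haul and
catch CSVs (schemas in `?read_survey_tables`; `validate_inputs()` checks
them first). A command-line wrapper lives at `inst/scripts/run_pipeline.R`.

The packaged species trait table (31 deep-water species, eight traits,
feeding guilds, L_max) is available via `load_reference_traits()`.

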