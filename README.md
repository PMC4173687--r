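# glottorisk

Spatial macroecology of language extinction risk, in R.

Many of the world's languages are spoken in small areas by few people, and
a substantial fraction is losing speakers rapidly. `glottorisk` implements,
as a tested and reusable pipeline, the quantitative machinery needed to
study this problem the way conservation biogeographers study species:

1. **Risk components per language** — range size (total equal-area polygon
   area, km²), speaker population size, and the speaker growth rate *r*,
   estimated as the year coefficient of a Poisson log-link GLM fitted to
   irregular survey series of speaker counts (so `exp(r)` is the annual
   growth ratio, comparable with the global human population growth ratio
   of about 1.016/yr). Series are eligible when they hold at least three
   records with at least one non-zero count; a Kendall tau-b check guards
   against survey-timing circularity.
2. **Threshold relationships** — each pairwise relationship among the
   three components is fitted with null, linear, quadratic, and segmented
   (one-breakpoint) regressions and compared by AIC. The breakpoint
   ψ of the continuous two-segment model
   `y = b0 + b1 x + b2 (x − ψ)₊` is estimated by iterative linearization
   with a profile-search guard, with delta-method or bootstrap confidence
   intervals, and back-transformed to natural units (speakers, km²). The
   breakpoint in the growth-rate/population-size relationship is
   interpretable as a minimum viable population for languages.
3. **Equal-area gridding** — ranges are projected to a Behrmann
   equal-area cylindrical grid (default grain 192.9725 km ≈ 2° at 30°
   N/S); a cell contains a language when the range polygon covers any
   positive-area portion of it; per-cell medians of the components,
   covariate means, and latitudinal band summaries are computed, with
   cells under 50% land excluded.
4. **Driver inference** — per-cell responses are regressed on
   environmental and socioeconomic covariates with simultaneous
   autoregressive (SAR) error models, `y = Xβ + u`, `u = λWu + ε`, fitted
   by maximum likelihood with row-standardized distance-band weights; the
   neighbourhood distance is adopted by AIC; Moran's I (permutation test
   and correlograms) diagnoses residual spatial autocorrelation;
   collinearity is screened at |r| > 0.8 with tolerance reporting; and
   all-subsets model sets are reduced to the 95% confidence set by Akaike
   weights and model-averaged (conditional averaging, unconditional SEs,
   per-variable Σwᵢ importance).
5. **Threat categorization** — each language is assessed against IUCN Red
   List criteria A3, B1, C1, D1 and D2 (e.g. VU below 1000 speakers, VU
   below 20 km², VU when the estimated decline exceeds 30% over three
   25-year generations), and per-cell maps of threatened and extinct
   richness expose extinction-filter structure.

Because the global range and survey databases these methods were built
for are proprietary, the package ships a fully parameterized
**synthetic-world generator** (`synthetic_config()`, `generate_world()`)
that emulates their structure — lognormal range- and population-size
distributions, a growth-rate distribution centred near 1.016/yr with a
long left tail produced by a decline regime below a configurable
speaker-population threshold, spatially autocorrelated covariate fields,
and a ground-truth ledger — so every stage is testable end to end.

## Worked example

```r
library(glottorisk)

cfg <- synthetic_config(seed = 7)
world <- generate_world(cfg)
comp  <- compute_risk_components(world$records, world$series, world$grid)

## growth rate versus initial population size: candidate model comparison
pw <- pairwise_threshold_analyses(comp)
pw$growth_vs_initial_population$table
#>      family k log_likelihood       aic delta_aic
#> 1      null 2       1322.656 -2641.312 296.56749
#> 2    linear 3       1412.331 -2818.663 119.21650
#> 3 quadratic 4       1449.188 -2890.376  47.50365
#> 4 segmented 5       1473.940 -2937.879   0.00000

## driver inference for the per-cell median growth rate
mem   <- assign_languages(world$grid, world$records)
cells <- analysis_cells(
  summarize_cells(world$grid, mem, comp, world$covariates),
  "median_growth_rate")
wts <- distance_band_neighbors(cells[, c("x", "y")], 300)
mm  <- sar_multimodel(cells$median_growth_rate,
                      cells[c("gdp_per_capita", "annual_precipitation")], wts)
mm$averaged
#>               variable          coef           se   z_value   sum_wi important
#> 1       gdp_per_capita -0.0042872801 0.0009927346 4.3186568 1.000000      TRUE
#> 2 annual_precipitation -0.0005135936 0.0009788548 0.5246883 0.296833     FALSE
```

The AIC table shows the segmented (threshold) model outperforming the
null, linear and quadratic alternatives for the growth/population
relationship — the synthetic world generates a decline regime below a
minimum-viable-population threshold, and the model comparison detects it.
The model-averaged table recovers the generating driver structure: GDP
per capita (which the generator couples to speaker declines) carries a
negative coefficient with |z| > 2 and a summed Akaike weight near 1,
while the null covariate is unimportant.

A threat assessment is one call more:

```r
assessment <- assess_all(comp)
assessment$summary$by_criterion
#>  A3  B1  C1  D1  D2
#> 161 166 159 202  20
```

The whole chain — simulate → components → breakpoints → grid → sar →
average → assess → report — is orchestrated by `run_pipeline()` (see
`pipeline_config()`), or from a shell via
`inst/scripts/glottorisk-pipeline.R`. Every run writes CSV/GeoJSON
outputs plus a manifest with the seed, stage counts and content hashes;
identical configuration and seed give byte-identical outputs.

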