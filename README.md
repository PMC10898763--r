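# mobexpo

Mobility-based environmental exposure assessment and air-quality
perception-mismatch analysis.

## What this package is for

Personal air-pollution monitoring campaigns pair a portable PM2.5 sensor
with a GPS logger, recording both at 1-second resolution over a survey
window (typically two days), alongside a questionnaire on perceived air
quality, mental health and sociodemographics. Analysing such data raises
the *uncertain geographic context problem* (UGCoP): environmental context
measured in buffers around the home (**residence-based**, RB) can differ
systematically from context aggregated over the places a person actually
visited (**mobility-based**, MB), and regression conclusions can flip with
the choice.

`mobexpo` provides the full analysis chain for researchers working with
such campaigns:

- **Stream fusion** — linear sensor calibration `pm' = max(0, a·pm + b)`,
  aggregation of 1-second samples into half-open 1-minute windows (channel
  means, GPS-fix centroid), and the pooled two-day mean exposure.
- **Ring-buffer exposure metrics** — land-use density (fraction of buffer
  area in a class set) over ten circular/ring buffers (0–50 m up to
  450–500 m), for transport, green-space and open-space classes of a
  categorical 10 m land-use raster; 1-km facility density via a 1415 m
  acceleration grid; street-block population density. Each metric exists
  in RB form (around the home) and MB form (averaged over minute-level
  locations); population density is RB-only.
- **Perception-mismatch classification** — the two-day exposure is
  dichotomised by an *exact* one-dimensional 2-means split (enumeration of
  all contiguous splits of the sorted values; deterministic, globally
  optimal), perception (six-point item) is binarised at the 3|4 boundary,
  and each participant lands in one of four quadrants: `low-low` /
  `high-high` (accurate), `low-high` (overestimation), `high-low`
  (underestimation).
- **Statistical layer** — OLS models of perceived air quality with a
  per-buffer adjusted-R² sensitivity scan; multinomial logistic models of
  the quadrant (Newton–Raphson, `high-high` reference, Cox–Snell /
  Nagelkerke / McFadden pseudo-R²); Mann–Whitney RB-vs-MB comparisons;
  one-way ANOVA with Shapiro–Wilk and Levene pre-checks; VIF diagnostics.
- **A synthetic-city generator** — land-use raster, stratified-quota
  cohort, anchor-based 1-second trajectories, a known PM2.5 field, and
  latent-variable questionnaire responses — so the whole chain is testable
  by parameter recovery without any external data. Real data enters
  through the same documented CSV / GeoJSON / ASCII-grid formats.

## Worked example

A 60-participant demo study on a 2 × 2 km synthetic city:

```r
library(mobexpo)
cfg <- run_config(world = world_config(extent_m = c(2000, 2000),
                                       n_participants = 60), seed = 23)
res <- run_pipeline(cfg, out_dir = "runs/demo")

res$split
#> <exposure_split> n=60  low: n=30 (max 14.695)  high: n=30 (min 15.128)
#>   centroids 12.593 / 17.342, within-SS 196.9

table(res$analysis$quadrant)
#>   low-low high-high  low-high  high-low
#>        20        10        10        20

res$scan$selected
#>   method inner_m outer_m        r2     adj_r2   model_p
#> 1     MB     250     300 0.4275573 0.06182996 0.3298883
#> 2     RB     450     500 0.4164540 0.04363287 0.3746255

res$fits$multinomial_mb
#> <mismatch_fit> multinomial logit, n=60, reference 'high-high' (ridge fallback)
#>   logLik -31.655 (null -79.780); pseudo-R2: Cox-Snell 0.799, Nagelkerke 0.859, McFadden 0.603
```

Reading this: the exact 2-means split dichotomises the two-day exposures
at the interval (14.70, 15.13] µg/m³ — every participant at or below
14.70 is "low", everyone at or above 15.13 is "high". Crossing that with
the binarised perception item puts 30 of 60 participants in the accurate
quadrants and flags 20 as underestimators. The sensitivity scan reports,
separately for RB and MB designs, which ring buffer gives the most
explanatory perception model (adjusted R²); at n = 60 the models are
weak, as expected for a demo-sized cohort — the multinomial fit at this
size leans on its documented ridge fallback. `runs/demo/` now contains the
participant table, long-format exposure records, the scan table, model
tables, the land-use grid and GeoJSON layers, and a JSON manifest;
`make_report("runs/demo")` renders a Markdown summary with figures.

A command-line front end with `simulate` / `expose` / `analyze` /
`report` / `all` subcommands lives at `inst/cli/mobexpo.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mobexpo.R", package="mobexpo"))')" \
    all --seed 7 --out runs/demo
```

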