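---
title: "Mobility-based exposure assessment and perception mismatch: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobility-based exposure assessment and perception mismatch: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobexpo)
```

## The problem

How well do people's judgements of air quality track the air pollution they
are actually exposed to? Answering this requires (a) a personal exposure
measurement that follows people through their day rather than anchoring them
at home, and (b) a way to classify each person as perceiving accurately,
overestimating, or underestimating their exposure.

The measurement question is an instance of the *uncertain geographic context
problem* (UGCoP): environmental exposure estimates change with the spatial
delineation of "context". A residence-based (RB) measurement summarises land
use in buffers around the home; a mobility-based (MB) measurement aggregates
the same buffers over the locations a person actually visited. The two can
disagree substantially, and conclusions drawn from regressions on either can
differ. `mobexpo` implements both measurements, the perception-mismatch
classification, the statistical layer around them, and a synthetic-city
generator with known ground truth so that every stage can be validated by
parameter recovery rather than by eyeball.

## Pipeline overview

1. **Synthetic city** (`world_config()`, `generate_landuse_raster()`,
   `generate_participants()`, `generate_trajectory()`,
   `generate_sensor_stream()`, `generate_questionnaire()`): a categorical
   10 m land-use raster with 27 classes, two communities of quota-sampled
   participants, anchor-based two-day 1-second trajectories, co-registered
   PM2.5/humidity/temperature streams, and questionnaire items from a
   latent-variable model with known coefficients.
2. **Stream fusion** (`apply_calibration()`, `aggregate_minutes()`,
   `two_day_exposure()`): linear sensor calibration with truncation at zero,
   half-open one-minute windows with channel means and fix centroids, and
   the pooled two-day mean PM2.5 exposure.
3. **Exposure metrics** (`ring_family()`, `landuse_density()`,
   `rb_exposures()`, `mb_exposures()`, `facility_density()`,
   `population_density()`): land-use densities over ten contiguous
   circular/ring buffers from 50 m to 500 m at 50 m steps, a 1-km facility
   density on a 1415 m acceleration grid, and street-block population
   density (RB only).
4. **Scoring** (`composite_score()`, `cronbach_alpha()`,
   `binarize_perception()`, `encode_covariates()`): 4-item mental-health
   (range 4-24) and 3-item respiratory (3-18) sums, internal-consistency
   diagnostics, the good/poor split of the six-point perception item at the
   3|4 boundary, and the 1-7 income / 1-6 education codings.
5. **Mismatch classification** (`kmeans_split()`, `assign_quadrant()`):
   exact one-dimensional 2-means dichotomisation of exposure crossed with
   binarised perception into the four quadrants low-low and high-high
   (accurate), low-high (overestimation), high-low (underestimation).
6. **Models** (`fit_linear_perception()`, `fit_multinomial_mismatch()`,
   `sensitivity_scan()`, `compare_rb_mb()`, `group_anova()`,
   `vif_diagnostics()`): OLS perception models per buffer and method with
   an adjusted-R² selection scan, multinomial logit of the quadrant with
   high-high as reference, Mann-Whitney RB-vs-MB comparisons, ANOVA with
   Shapiro-Wilk/Levene pre-checks, and VIF screening.

`run_pipeline()` orchestrates all of it behind one master seed and writes
plain-text artifacts (CSV, GeoJSON, ESRI ASCII grid, JSON manifest);
`make_report()` renders a Markdown summary.

## The synthetic world and what it does (not) emulate

The generator's default conditions are fixed once and mirror the study
design they stand in for: 210 participants split 105/105 over two
communities (a dense old-urban community A and a residential new town B),
quota-sampled on gender x age band x income group x employment with
largest-remainder rounding, two survey days (one weekday, one weekend day)
of 1-second GPS and sensor samples (2 x 86,400 fixes per person), a 27-class
land-use raster in which green space is three classes, open space one, and
transportation four.

The synthetic PM2.5 field is

\[ pm(s,t) = B + G\,(x(s)/W - \tfrac12) + I\,T(s) - D\,Gr(s)
          + A \sin\!\big(2\pi (t - 6\mathrm{h})/24\mathrm{h}\big) + \varepsilon \]

with baseline \(B = 15\), regional west-east gradient \(G = 20\), transport
increment \(I = 12\), green decrement \(D = 6\), diurnal amplitude
\(A = 4\) µg/m³ and iid noise sd 3; \(T\) and \(Gr\) are disc-smoothed
(50 m) transport/green indicators in [0, 1]. The regional gradient is what
separates the two communities' ambient levels and spreads the two-day
means over a realistic low-tens range; the transport/green terms create the
local structure that makes RB and MB measurements diverge. With noise and
amplitude disabled the field is a deterministic function of location, so
analytic spot checks pass at machine precision — this is exploited
throughout the tests.

Perception is generated from an ordered-latent-variable model: a linear
predictor over participant covariates (exposure, age, gender, mental-health
score, MB transport and green densities at the 350-400 m ring) plus
Gaussian noise, cut at five strictly increasing thresholds into the
six-point item. The mental-health and respiratory items load on one common
factor each (loading 1.1, item noise sd 0.8 on the six-point scale), which
puts the 4-item Cronbach's alpha in the high-0.8s — the internal-consistency
regime such instruments are reported to reach.

What the generator does *not* emulate: road-network routing (walks are
straight lines between activity anchors), indoor/outdoor attenuation,
sensor drift or humidity-dependent calibration error, and any real
geography. Passing tests therefore demonstrate the *machinery* — metric
correctness, classifier exactness, estimator calibration — not that any
substantive coefficient estimated from real survey data is right.

## Key numerical and design choices

- **Buffers.** A raster cell belongs to the ring `inner <= d < outer` by
  its *center* distance; the half-open interval partitions the 500 m disc
  exactly across the ring family, so no cell is counted twice and densities
  over the full 27-class partition sum to 1. No partial-cell weighting.
- **MB aggregation** is the arithmetic mean of per-minute-point ring
  densities, not the density of a dissolved buffer union; the per-point
  reading follows from treating each GPS point as its own context. By
  default minute locations are snapped to their 10 m cell center and
  densities memoised per distinct cell (`snap = TRUE`), a <=7 m
  approximation far below the 50 m buffer resolution that makes cost scale
  with distinct visited cells rather than minutes.
- **Minute windows** are half-open `[t, t+60)`, aligned to the whole minute
  of the first sample; the representative location is the centroid of the
  window's fixes (symmetric and jitter-stable, unlike first/last-fix
  rules). Missing minutes are dropped, never imputed, and the two-day
  exposure pools minutes rather than weighting days equally — with equal
  coverage the two coincide; with unequal coverage pooling weights minutes
  equally, which is the better match to "mean of recorded values".
- **Calibration** is `max(0, slope * pm + intercept)` with coefficients
  supplied by configuration, standing in for an external co-location model.
- **2-means dichotomisation** is computed exactly: for k = 2 in one
  dimension the optimum is a contiguous split of the sorted values, so all
  n-1 split points are enumerated and the global within-SS minimum taken.
  This removes the seed/initialisation ambiguity of Lloyd-style k-means;
  ties (to numerical tolerance) break toward the smaller low cluster. The
  boundary is reported as the pair (largest low value, smallest high
  value), matching the two-interval presentation used for such splits. The
  contiguity property itself is verified empirically in the tests against
  brute force over *all* 2-partitions at n <= 12. Exposures are pooled
  across communities before splitting (one threshold pair, not two).
- **Multinomial fitting** is full Newton-Raphson with step-halving
  (log-likelihood provably non-decreasing per iteration), tolerance 1e-8 on
  the log-likelihood, at most 200 iterations, and a 1e-6 ridge fallback
  when the Hessian is singular or quasi-complete separation inflates the
  coefficients (flagged in the result). `nnet::multinom` serves as an
  independent cross-check in the test suite, never as the implementation.
  Pseudo-R²: Cox-Snell \(1-(L_0/L_1)^{2/n}\), Nagelkerke (Cox-Snell
  normalised by its maximum), McFadden \(1-\log L_1/\log L_0\).
- **Model selection** in the sensitivity scan uses adjusted R² ("highest
  explanatory power" is ambiguous between R² and adjusted R²; adjusted R²
  is fixed here and both are emitted). Ties break to the smallest outer
  radius. The perception response is modelled by OLS despite its ordinal
  scale — fidelity to the analysis being reproduced — with an ordered-logit
  engine available behind `engine = "ordered_logit"` for sensitivity.
- **Mann-Whitney** uses exact enumeration below 20 per arm without ties and
  the tie-corrected normal approximation otherwise (no continuity
  correction, so identical samples give p = 1).
- **Facility density** is reported per m² of the 1-km disc; the 1415 m
  index grid guarantees the 3x3 neighborhood scan is exactly equivalent to
  a full scan because 1415 m exceeds the 1-km search radius. Only relative
  ordering of this quantity enters the models, so the unit convention is
  configurable in interpretation.
- **Population density** exists only as an RB quantity (real-time
  population cannot be attached to minute locations); boundary points are
  assigned to the lower block id deterministically.
- **Degenerate inputs** fail loudly and early: all-identical exposures
  (degenerate split), empty quadrant classes (with the instruction to
  enlarge the cohort), missing questionnaire items (no imputation),
  non-positive calibration slopes, rings containing no cell centers.
- **GPS jitter** sd (default 3 m) is a configuration knob, not a claim
  about receiver error.

## Validation by recovery, and problem sizes

Because the real survey data behind the published coefficients are not
available, validation is anchored on properties the machinery must have:

- ring densities equal exhaustive per-cell enumeration on random fixtures;
- the exact 2-means split equals brute force over all 2-partitions, and on
  an equal mixture of N(8, 2²) and N(22, 3²) (n = 400) the boundary lands
  between the modes in ≥95% of seeds;
- on a designed commuter cohort (homes in residential zones, workplaces in
  a central transport district, minutes split 60/25/15 between
  home/work/path), MB transport density exceeds RB with Mann-Whitney
  p < 0.001, and the slope of (MB − RB) on RB is negative — the
  neighborhood-effect-averaging signature, by which mobility pulls
  individually extreme residential exposures toward the population mean;
- OLS and multinomial fits on cohorts simulated from known coefficients
  achieve 95%-CI coverage within [90%, 99%] over 100 replicates
  (n = 500 and 800);
- when only the 150-200 m ring's green density enters the true model, the
  adjusted-R² scan selects that ring in ≥80% of replicates (the noise sd in
  that experiment is set to half the signal sd at design time — strong but
  not degenerate);
- identical seeds reproduce every artifact byte for byte.

Problem sizes in the tests and the acceptance script (a 210-participant
full run on a 3 x 3 km world, a 60-participant demo on 2 x 2 km, 100
recovery replicates, 25 scan replicates) are the package's chosen
validation scale: large enough for the asymptotics the checks rely on,
small enough to re-run casually on a laptop.

On the default synthetic geometry the full-cohort RB-vs-MB contrast is
strong for green and open space but can be weak for transport at wide
rings — thin 20 m corridors contribute little area to a 300 m annulus
around either homes or workplaces. The designed commuter cohort, whose
employment core is an extended transport district, is the fixture that
carries the transport contrast; this mirrors the fact that the size of the
RB/MB divergence is a property of the city and the mobility pattern, not
of the estimator.

## Known limitations

- The anchor-based mobility model produces no route variability, transit
  trips, or within-day location noise beyond jitter; MB exposures are
  correspondingly smoother than real activity-space measurements.
- The latent perception model is linear with homoscedastic noise; real
  perception items show floor/ceiling effects the cutpoint model only
  partially reproduces.
- Income and education enter the models as integer-coded continuous
  variables, inheriting that analytical convention with its known
  coarseness.
- The histogram of synthetic two-day exposures is narrower than a real
  urban cohort's (no indoor sources, cooking, or smoking
  microenvironments).
- GeoTIFF raster IO is not provided; the ESRI ASCII grid (plus GeoJSON for
  vectors and CSV for streams) is the interchange surface.
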