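---
title: "Estimating and projecting the temperature sensitivity to leaf-area change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and projecting the temperature sensitivity to leaf-area change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laisens)
```

## The model

`laisens` implements a three-stage pipeline for quantifying how vegetation
density (leaf area index, LAI) affects near-surface air temperature, and how
that effect plays out under future greening and climate change.

### Stage 1 — space-for-time decomposition

The premise: over a month and between two years, the temperature change at a
cell decomposes as ΔT = ΔT_lai + ΔT_res, where ΔT_res is the large-scale
climate signal shared with the cell's neighbourhood and ΔT_lai is the local
vegetation contribution. At *reference* cells — within a search radius and
with stable LAI (|ΔLAI| below 0.1 m²/m²) — the vegetation term is negligible,
so their observed ΔT estimates the climate signal. The package combines the
references by inverse-distance weighting (`idw_residual()`) and subtracts
(`local_delta()`; `decompose_local_signal()` runs the whole grid with a
vectorized shift-and-accumulate engine that agrees with the per-cell
operations — the tests check the two routes against each other).

Assumptions worth stating plainly:

* the climate signal really is shared across the neighbourhood — the method
  cannot separate a vegetation signal from climate variability at scales
  smaller than the reference radius;
* LAI-stable cells have negligible vegetation-driven temperature change;
* effects are local: teleconnections from remote land-cover change are not
  resolved (a known limitation, not a target of this package);
* deltas are always oriented later-minus-earlier; each unordered year pair is
  used once.

Per cell and month, all unordered pairs of the baseline years form an
ensemble of sensitivity samples — per-record ratios ΔT_lai/ΔLAI (not a pooled
regression; the ratio form is what the per-pair s.d. filter below is defined
on). With 12 baseline years this gives up to 66 samples per cell-month.

### Stage 2 — regime-specific response surfaces

Samples split at 1 % monthly snow cover (between-year mean). In the snow
regime the albedo contrast dominates and the response is linear in LAI change
(°C per m²/m²); in the snow-free regime turbulent-flux partitioning dominates
and the response is expressed per unit ln LAI, capturing the saturation of
the effect at high LAI. Each regime's sensitivity is a bivariate quadratic —
design (x², y², xy, x, y, 1) — in (snow cover, shortwave) or (evaporation,
shortwave), fitted by unweighted OLS on the pooled global sample set
(`fit_quadratic_surface()`). `published_surfaces()` provides the
observation-derived coefficient sets as a fixture.

### Stage 3 — projection and attribution

`biophysical_delta_T()` evaluates the surfaces at each scenario run's own
drivers, month by month, and multiplies by the cumulative LAI change from the
run's baseline-year climatology (linear ΔLAI in the snow regime, Δln LAI in
the snow-free regime). Cumulative change — not trend-slope times elapsed
years — reproduces the time-series shape of the projected signal and makes
the factorial attribution exact; a slope-based variant would only differ by
smoothing. `factorial_attribution()` computes:

* **all effects**: future drivers, future LAI;
* **LAI effect**: baseline-climatology drivers, future LAI;
* **climate effect**: all minus LAI — exact by definition;
* **driver terms**: all-effects minus the variant with one driver held at its
  baseline climatology.

Quadratic surfaces and regime switching make the driver terms non-additive;
the shortfall is stored as `closure_residual` rather than hidden, because
exact separation of interacting drivers is impossible in principle. With
linearized surfaces and no regime flips the residual vanishes (machine
precision), which the tests assert.

The biochemical channel is deliberately simple: avoided warming of 2.2 °C
per Tt C of vegetation-carbon gain, linear in ΔB
(`biochemical_delta_T()`; negative return = cooling).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `radius_km` | 50 | km | reference search radius; the native-resolution value. **Scales with the grid**: on the 60×120 synthetic grid (~259 km cells) the equivalent neighbourhood is 400 km (~1.5 cells) |
| `stability_threshold` | 0.1 | m²/m² | below: reference cell; above: target cell |
| `snow_threshold` | 1 | % | regime split on between-year mean snow cover |
| `sd_filter` | 0.2 | response units | excludes cells whose per-pair sensitivity s.d. exceeds it |
| `dlnlai_floor` | 0.05 | ln units | guards snow-free ratios against tiny denominators; mirrors the 0.1 m²/m² linear guard (the exact guard used historically is unstated, so it is configurable) |
| `conversion` | `"finite"` | — | per-m²/m² conversion of ln-scale sensitivity: ln(LAI+1) − ln(LAI) under the 1 m²/m² change assumption; `"infinitesimal"` (1/LAI) available |

Distance is haversine on a 6371 km sphere, center to center — the standard
latitude-safe choice; whether the original analysis used great-circle or a
fixed cell radius is not documented, and at 0.05° resolution the difference
is immaterial.

## Design decisions that were genuinely open

* **Stability per year pair.** LAI stability of a reference is assessed on
  the pair being differenced, not once over the whole record: the premise
  ΔT ≈ ΔT_res at a reference is a per-pair statement. A whole-period reading
  is defensible; per-pair is the stricter and self-consistent one.
* **s.d. filter grouping.** The 66-sample ensemble exists per cell *and
  month*, so the 0.2 filter is applied per (cell, month) group; grouping is a
  parameter (`by=`). The same threshold applies to snow (per m²/m²) and
  snow-free (per ln unit) responses alike.
* **Monthly averaging.** The mean annual sensitivity map weights months
  equally, not by sample availability.
* **Per-regime fits are global**, pooling all cells, months and pairs —
  matching the two published global equations; fits on per-record ratios,
  not on binned averages.
* **Projection baselines.** The "current climate" branch of the attribution
  uses each run's own baseline-year monthly climatology, not an external
  observational climatology, so the factorial contrast stays within one
  model's world.
* **Quantile convention.** Ensemble quartiles use linear interpolation
  between order statistics (R type 7) so box summaries are deterministic and
  an odd ensemble's median is a member value.
* **Sign conventions.** Negative ΔT is cooling everywhere; mitigation
  summaries report cooling magnitudes as positive, labelled columns.

## What the synthetic world does and does not emulate

`generate_baseline_obs()` constructs
T = T_clim + C + V + ε with:

* **C**, the large-scale anomaly: per month-year random amplitudes on smooth
  spatial modes. The default is a single spatially uniform mode — an infinite
  correlation length — because the noise-free recovery contract (every
  retained sample equals the injected surface value to 1e-6) requires
  neighbours to share C *exactly*; low-order polynomial/harmonic modes are
  available (`n_climate_modes`) to stress the shared-signal assumption.
* **V**, the injected vegetation signal: the true surfaces (default: the
  published coefficient sets) evaluated at the cell-month drivers, times the
  LAI anomaly (linear in the snow regime, ln in the snow-free regime).
* **Drivers** as deterministic latitude–month templates plus static per-cell
  jitter: snow cover grows with |latitude| and winter, shortwave follows a
  declination-like insolation curve, evaporation increases with LAI and
  radiation. Time-invariance of drivers makes between-year driver means exact
  and recovery testable at machine precision.
* **LAI**: stable cells on a deterministic lattice (fraction 1/3 by default,
  guaranteeing every changing cell a reference within the neighbourhood —
  asserted at generation, with an explicit failure otherwise); changing cells
  get per-year anomaly levels spaced 0.12 m²/m² apart so every pair clears
  the 0.1 threshold and no changing cell masquerades as a reference.
* **ε**: independent Gaussian observation noise (default 0; the acceptance
  checks run both noise-free and at 0.1 °C).

What it does **not** emulate: retrieval artifacts (orbital gaps,
solar-zenith effects, winter high-latitude noise — a config hook exists but
defaults off per scope), cloud contamination, non-local teleconnections,
land-use change, or vegetation dynamics. A green recovery test therefore
establishes the *estimator's* correctness under the method's own premises —
not the validity of those premises for any real satellite record.

`generate_scenario_ensemble()` builds model×scenario trajectories with
monotone ensemble-mean greening proportional to scenario strength, declining
snow, rising evaporation (reversed at 10 % rate in the 15–30° arid band),
mild shortwave dimming, vegetation carbon coupled to global LAI through one
constant (0.4 Tt C per unit global-mean LAI), and per-model multiplicative
trend perturbations (s.d. 0.15, roughly the spread of a mid-size model
ensemble). A global land-warming series (5 °C by 2100 at strength 1, the
scale of a high-emission land signal) is attached so relative mitigation is
computable — it is a synthetic bookkeeping series, not a modelled field. The
default geometry is a 2°-spacing meridional strip covering all climate
zones; the spacing is the physically meaningful quantity, the longitudinal
extent is a desk-scale choice.

Scenario strengths default to 0.25/0.5/0.75/1 (SSP126…SSP585): equal spacing
is a neutral choice given that only the strict ordering is specified.

## Numerical choices

* OLS solves equilibrated normal equations (columns scaled by their root
  diagonal): the raw design spans ~10 orders of magnitude (SW² vs 1) and
  would otherwise look rank-deficient in double precision. The normal-
  equation route is order-independent, hence deterministic under row
  permutations.
* The ground-truth oracle (`ground_truth_delta_T()`) and the projection
  kernel are separate implementations written with the same elementary
  operation order, so the equivalence test can demand bit-for-bit equality.
* Missing data are never imputed: masked cells drop out of every weighted
  statistic; an empty aggregation domain is an error, not a silent NaN.
* Degenerate inputs fail loudly: zero reference distance, empty reference
  list, degenerate LAI range in the transition binning, constant fields in
  map correlation.

## Known limitations

* The desk-scale grids make the 50 km literal radius meaningless; users of
  real 0.05° products should pass `radius_km = 50`, synthetic-world users the
  resolution-scaled equivalent. The package does not guess.
* Attribution residuals grow where snow cover crosses the 1 % threshold
  between factorial variants; the residual series is the honest account.
* Relative-mitigation summaries depend on the synthetic warming series when
  run on generated ensembles; with real model output the user supplies the
  warming trajectory.
* Non-local (teleconnection-mediated) effects are out of scope by design.
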