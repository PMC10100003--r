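---
title: "Methods: carbon accounting from L-VOD and land-cover bookkeeping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon accounting from L-VOD and land-cover bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vodcarbon)
library(data.table)
```

## The accounting problem

Two largely independent lines of evidence exist for forest carbon change.
Top-down: L-band vegetation optical depth (L-VOD), a passive-microwave
attenuation index retrieved at ~0.25° that increases monotonically with
vegetation water mass and hence above-ground carbon (AGC). Bottom-up: a
bookkeeping model that assigns carbon losses and gains to mapped land-cover
transitions using reference densities and response curves. This package
implements both limbs and their combination: the bookkeeping model explains
deforestation, forest-edge and non-edge degradation, and secondary-forest
regrowth; whatever satellite-observed change remains in cells dominated by
old-growth forest is attributed to old-growth processes (drought mortality,
growth enhancement, ...) by residual.

Everything is exercised end-to-end on synthetic scenes whose per-process
fluxes are known exactly, so each stage has an oracle.

## Top-down limb: from daily VOD to an annual AGC series

**Filtering.** Four stages, in a fixed order, each logged with the number
of observations removed:

1. *Quality and inundation masks.* Observations with a nonzero quality
   bitmask are dropped, as are all observations of cells whose inundated
   fraction exceeds 0.25 — sub-canopy flooding inflates VOD independently
   of biomass.
2. *RFI.* TB-RMSE (the mismatch between observed and modelled brightness
   temperatures) above 8 K indicates radio-frequency interference; those
   records are excluded.
3. *Orbit reconciliation.* Ascending and descending passes are partially
   independent retrievals. Per cell and trimester (calendar quarters
   JFM/AMJ/JAS/OND, chosen to align with the January–April reporting
   window; configurable), if the two orbit means differ by more than 0.05
   the trimester's records with TB-RMSE > 5 K are discarded — by default
   from both orbits, since "the respective data" is ambiguous; the
   alternative (only the orbit farther from the pooled mean) is a flag.
   Days observed by both orbits then keep the record with the lower
   TB-RMSE (ties resolved toward ascending).
4. *Outliers.* Within each cell-trimester with at least 3 records, values
   beyond 2 standard deviations from the trimester mean are removed. Mean
   and SD are computed once on the incoming set, not iterated: the 2-SD
   rule is scale-free, so iterating it would keep eating the tails of any
   distribution. For the same reason the 100%-retention guarantee for
   uncontaminated streams is exact only when the underlying signal is
   trimester-stationary (the static-world limit in the tests); a real
   declining signal loses a small fraction of kink-adjacent points by
   design.

All five thresholds (8 K, 5 K, 0.05, 25%, 2 SD) are strict inequalities.

**Seasonal–trend decomposition.** The classic decomposition for long
atmospheric records: an OLS fit of a quadratic polynomial in time plus the
first two annual harmonics; the fit residuals are interpolated to a daily
grid and low-pass filtered with a sixth-order frequency response
`H(f) = 1/(1 + (f/fc)^6)`. The *smoothed* series adds the 80-day-cutoff
residual to the full fit; the *trend* series adds the 667-day-cutoff
residual to the polynomial alone, removing seasonality (the annual
harmonic leaks into the trend at < 3% amplitude). Cutoffs and polynomial
order are exposed in the function arguments. The residual series is
mirror-padded before the FFT so circular wraparound does not ring into the
first and last years — exactly where the index windows sit.

**Annual indices.** Three per cell-year over the closed 1 January –
30 April window (wet season, when plant water content is most stable):
maximum of the smoothed curve, mean of the smoothed curve, mean of the
trend curve. A window with fewer than 20 retained observations is flagged
missing; missing propagates, never zero.

## Calibration to AGC

Each index is calibrated *independently* against a reference biomass field
for the reference year with the saturating four-parameter logistic
`AGC(V) = d + (a − d)/(1 + exp(−b (V − c)))` (floor `d`, asymptote `a`,
inflection `c`, steepness `b`). The functional body is a pluggable
strategy, so a different four-parameter saturating form can be substituted
without touching the rest of the pipeline. Per-method calibration matters:
the smoothed-curve maximum carries the seasonal amplitude as a
near-constant offset, which the fit absorbs into `c`.

Fitting is Levenberg–Marquardt least squares with 8 deterministic starts
spanning the observed index range (saturating forms have local minima);
non-finite curve evaluations are replaced by the sentinel `1e10` during
fitting and prediction. A constant-index input is rejected; a constant
reference target returns the exact flat solution. Standard errors come
from the fit covariance. Identifiability requires the calibration pairs to
span a real stretch of the curve, including its inflection — with all
cells bunched near saturation, the fitted local slope at the operating
point (which multiplies every retrieved *change*) is unconstrained. The
synthetic scene generator therefore produces a wide cross-cell biomass
range (below).

The AGC series is the mean of the three per-method estimates; their SD is
carried into the uncertainty budget. Cell-years missing any method are
masked. Finally, cells showing a year-over-year increase above
20 Mg C ha⁻¹ — far beyond the biome's plausible accumulation of up to
~6 Mg C ha⁻¹ yr⁻¹ — are masked entirely as retrieval anomalies.

## Bottom-up limb: land-cover engine

From annual fine-grid class rasters (forest / pasture / agriculture /
bare, remappable via a YAML vocabulary) and boolean disturbance-event
rasters, all at the native fine resolution before any aggregation:

- **Deforestation**: forest in year *t−1*, pasture/agriculture/bare in
  year *t*; booked entirely to the detection year.
- **Secondary forest**: non-forest for at least one year, then forest;
  age is the run of consecutive forest years (age 1 in the first year).
  Clearing resets the age; pixels forested since the start of the record
  can never be identified as secondary.
- **Edge zones**: non-secondary forest within 120 m (Euclidean, pixel
  centres, inclusive — 4 pixels at 30 m) of currently cleared, previously
  forested land. Edge age increments while the pixel stays forest; edge
  history is never erased by regrowth of the adjacent clearing, since the
  biomass loss has already been incurred.
- **Non-edge degradation**: disturbance events on old-growth pixels only.
  Events on edge pixels are excluded (edge losses are modelled
  explicitly), events on secondary forest are ignored (regrowth is
  tracked by the growth curve), and repeat events on already-degraded
  pixels are not double-counted by default (`recurrent_degradation_losses`
  flips this). The degraded-ever baseline is a ratchet.
- **Old-growth**: forest, never degraded, not secondary, not edge.

State precedence for non-secondary forest is edge > degraded >
old-growth. Secondary forest *keeps its state inside edge buffers*: almost
all regrowth is adjacent to cleared land, so classifying it as edge would
replace the growth curve with an old-growth-referenced edge loss and
erase the secondary-growth term entirely. A degraded pixel later reached
by an edge buffer becomes edge with the degradation loss as a floor
(below), so no spurious gain is ever booked.

The five states tile every pixel every year; fractional covers per coarse
cell are exact pixel counts.

## Bookkeeping fluxes

Reference densities come from the static biomass map masked by old-growth:
per cell, the median over the >90%-old-growth cells within a 1° circular
window (widened to 2° and then flagged if empty). The non-edge degradation
loss factor is the relative gap between the old-growth and degraded
reference medians, `(126.4 − 81.78)/126.4 = 35.3%` with the default
reference values.

Per process and cell-year (losses negative, gains positive; all
density-to-stock conversions use exact areas):

- *Deforestation*: −area × prior-state density — `ref_og` for old-growth,
  `ref_og (1 − λ)` for degraded, `ref_og (1 − loss(age))` for edge (with
  the λ floor if the pixel was degraded before becoming edge), and
  `growth(age)` for secondary stands.
- *Edge degradation*: −`ref_og` × [loss(a) − loss(a−1)] × area per edge
  area at age *a*; increments telescope to the cumulative loss.
- *Non-edge degradation*: −area × `ref_og` × λ, once per newly degraded
  pixel.
- *Secondary growth*: area × [growth(a) − growth(a−1)], with growth(1) for
  new stands (the same formula, since growth(0) = 0). Losses from cleared
  secondary forest are booked under deforestation.

**Curves.** Secondary regrowth is Chapman–Richards,
`AGC(t) = A (1 − e^{−kt})^θ`, defaults A = 110 Mg C ha⁻¹, k = 0.035 yr⁻¹,
θ = 1.6 — a stand reaches roughly a third of old-growth density by age 20,
consistent with Amazonian chronosequences. Edge loss is saturating,
`loss(a) = L∞ (1 − e^{−ra})`, defaults L∞ = 0.36, r = 0.2 yr⁻¹ — edge
forest asymptotically loses about a third of its carbon, accruing over
about a decade. Both are truth parameters of the synthetic world and
configuration values of the model; published parameter sets can be dropped
in directly.

## Residual attribution of old-growth change

For every cell-year, the satellite stock change is
`ΔAGC = (agc_mean(t) − agc_mean(t−1)) × area`. In reference cells (>90%
old-growth cover), the old-growth change density is defined as the cell's
own residual `(ΔAGC_lvod − ΔAGC_modelled) / old-growth area`. Non-reference
cells receive the circular median of the reference-cell residual densities
within 2.5°, widened to 5°, and are flagged (and excluded from the
old-growth flux, with a warning) if no reference cell lies within the
widened radius. Using the cell's own residual in reference cells — rather
than a median that includes neighbours — is what makes the combination of
processes equal the satellite change *exactly* there, which is the stated
property of the attribution and the package's closure test.

**Uncertainty.** The per-process sigmas are configurable relative
uncertainties (defaults: deforestation 0.216 — the relative spread of the
old-growth reference median, ±27.3 on 126.4 —, non-edge degradation 0.30,
edge 0.25, secondary growth 0.20); the old-growth sigma uses the MAD of
the reference-cell residual densities per year times the cell's old-growth
area. Annual sigmas combine by root sum of squares by default; plain
summation is available as the conservative alternative.

## The synthetic world

`generate_scene()` forward-simulates the land-cover state machine above
and books per-process truth fluxes with the same reference densities and
curves the model is configured with; the per-cell true AGC density series
accumulates those fluxes from the year-1 stocks. Design choices:

- **Geometry**: an abstract pixel lattice (default 30 m pixels, 64×64 per
  0.25°-analog cell) with planar-degree cell centres; no real CRS is
  needed for testing, and real rasters can be substituted at the same
  interfaces.
- **Heterogeneous cover**: 15% of the scene starts as long-cleared pasture
  under a steep spatial gradient (weights `exp(9u)` for initial cover,
  `exp(7u)` for annual clearing and disturbance pressure, with `u`
  increasing toward one corner). This emulates a deforestation arc
  bordering an intact interior, and it is load-bearing: the cross-cell
  AGC range (~5–126 Mg C ha⁻¹) spans the calibration curve's dynamic
  range, keeping the fit identifiable, while the interior provides the
  >90%-old-growth reference cells the residual attribution needs.
- **Rates**: 1% of forest cleared per year (clustered patches), 0.5% of
  forest disturbed per year, 2% of non-forest regrowing per year —
  frontier-region magnitudes that produce all five processes at
  comparable order within a decade.
- **Old-growth drift**: a uniform −0.5 Mg C ha⁻¹ yr⁻¹ density decline of
  old-growth pixels, the "other processes" signal the residual
  attribution must recover. The magnitude is a drought-decade value:
  plot networks report losses up to ~1 Mg C ha⁻¹ yr⁻¹ in drought years
  and near-neutral balance otherwise. Deforestation of old-growth is
  booked at the static reference density on both sides of the closed
  loop, so the drift affects standing stocks only.
- **Observations**: both orbits every 2 days (the middle of the 1–3-day
  revisit range) on a common day grid, so same-day orbit pairs exercise
  the combination rule constantly. VOD is the inverse calibration curve
  applied to the true density (anchored at 1 March, the midpoint of the
  index window, and interpolated piecewise-linearly), plus a sinusoidal
  seasonal cycle peaking in the wet season, Gaussian noise (default
  sd 0.02), a constant ascending-orbit offset (0.02), RFI spikes with
  TB-RMSE ~ Uniform(8, 20) K — guaranteeing the 8 K rule is exercised
  from both sides, with clean TB-RMSE ~ Uniform(1.5, 6) K — and a 1%
  quality-flag rate.

What the generator does **not** emulate: radiative-transfer physics of the
retrieval (VOD is generated exactly on the calibration curve), sub-canopy
flooding dynamics (inundation is a static per-cell fraction), spatial
variability of old-growth biomass (the reference density is uniform, so
reference extraction is exact by construction), classification error in
the land-cover maps, and spatially correlated observation noise. Passing
closed-loop tests therefore demonstrates that the accounting machinery is
self-consistent and that the estimators are unbiased under the stated
noise model — not that the real retrieval or the real maps are accurate.

## Numerical choices and degenerate inputs

Strict inequalities everywhere a threshold is worded strictly; same-day
orbit ties broken toward ascending; the seasonal–trend fit requires at
least 8 distinct dates spanning 2 years; `nlsLM` runs with
`ftol = ptol = 1e-14` and up to 200 iterations per start; empty transition
tables yield empty flux tables rather than zeros; missing data propagate
as NA and are never imputed. The Mann–Kendall test uses the tie-corrected
variance with a continuity correction (cross-checked against the
Kendall-tau test as an independent oracle); Theil–Sen significance is only
defined for four or more years.

## Problem sizes and what the tests show

Unit tests run on 4×4-cell scenes with 16× subdivision over 6 years;
the acceptance-scale checks run the full satellite limb on an 8×8-cell
scene with 64× subdivision over 9 years (512×512 fine pixels), the size at
which the residual attribution has of order 16–40 reference cells per
year. At the default observation noise the four bookkeeping processes are
recovered exactly (they do not depend on the satellite stream) and the
biome net change over the study period is recovered to within a few
percent; the *per-year* old-growth term is variance-limited — its
reference-median error is of the same order as the drift signal — which is
the honest behaviour of a residual estimator at this problem size, and the
reason old-growth recovery is assessed on period totals.

## Limitations

No committed-emissions accounting (decay pools, soils, belowground
biomass); no CO₂-equivalent conversion; planar-degree distances (no
cosine-latitude weighting in the synthetic world); the edge and regrowth
curves are single-parameterization (no regional stratification); and the
residual attribution inherits every bias of the satellite limb — a
calibration slope error at the old-growth operating point propagates
one-to-one into the old-growth term.
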