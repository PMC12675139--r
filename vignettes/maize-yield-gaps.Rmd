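---
title: "Water-driven maize yield gaps with an adaptive growing season"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-driven maize yield gaps with an adaptive growing season}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`maizegap` simulates grain maize production cell by cell with a minimal
water-driven crop model, runs it under three management regimes, and
aggregates the results into the quantities a yield-gap analysis maps:
actual, water-limited and potential yield (Ya, Yw, Yp), the yield gaps
YGw = (1 − Ya/Yw)·100 and YGp = (1 − Ya/Yp)·100, water productivity, sowing
dates, cycle lengths, suitability classes and crop-failure counts, for a
baseline and a warmed climate. This vignette is the package's own account
of the model, its assumptions, and the design choices made where the
design was genuinely open.

## The model chain

```{r, eval = FALSE}
library(maizegap)
out <- run_experiment(run_config(seed = 1))
```

One experiment walks six stages: synthetic weather generation → derived
climate drivers (FAO-56 ETo, growing degree days) → temperature-dependent
sowing → a daily water-driven growth simulation per management regime →
yield-gap and water-productivity statistics → ensemble/spatial
aggregation. All stochasticity lives in the weather generator; everything
downstream is deterministic.

## Synthetic weather

The generator replaces reanalysis/climate-model forcing with a
statistically similar synthetic: a sinusoidal annual temperature cycle
(peak mid-July) plus an AR(1) anomaly with stationary standard deviation
`anomaly_sd` and lag-one autocorrelation `anomaly_autocorr`; a two-state
wet/dry Markov chain for precipitation occurrence (stationary wet-day
frequency `wet_day_prob`, wet-after-wet persistence `wet_persistence`)
with gamma-distributed wet amounts (shape 0.75, a positively skewed,
drizzle-heavy distribution); relative humidity and wind as noisy
perturbations of their means; and shortwave radiation as extraterrestrial
radiation for the latitude and day of year times a wet/dry clearness
factor (0.25–0.45 on wet days, 0.55–0.75 on dry days). Scenario knobs are
a uniform warming offset `delta_T`, a multiplicative `precip_factor`
applied to wet-day amounts only, and a linear annual CO2 trajectory.

This family was chosen for its minimal parameter count and analytic
checkability: the wet-day frequency has a closed-form stationary value,
the warming offset is exactly additive in the temperatures, and the
precipitation scaling is exactly multiplicative under a shared seed. What
the generator does **not** emulate: spatially coherent weather across
cells (cells are independent draws), heat waves and dry spells beyond
what AR(1)/Markov persistence produces, humidity–temperature coupling,
and trends within a period. Passing tests therefore show that the *model
chain* behaves correctly under realistic marginal statistics, not that
any real region's yields are reproduced.

Small "climate-model" ensembles are emulated by giving each member a
distinct derived seed plus mild deterministic perturbations (±2–8%) of
`anomaly_sd` and `wet_day_prob`, so members differ in both noise and
climatology — mirroring the observation that inter-model spread involves
both. Member 1 is the unperturbed spec, and member order is stable.

Calendars are real: leap days are generated and all day-of-year logic
uses actual dates. CO2 is annual-resolution, repeated daily.

## Derived climate drivers

Reference evapotranspiration follows the FAO-56 Penman–Monteith daily
combination equation for a grass reference. Two places needed a
documented choice because daily mean relative humidity is the only
humidity variable in the forcing:

* actual vapour pressure is `ea = RH/100 · (es(Tmin) + es(Tmax))/2`, one
  of the FAO-56-sanctioned variants for mean-RH-only data;
* 10-m wind is converted to 2 m with the FAO-56 logarithmic profile
  factor `4.87 / ln(67.8·10 − 5.42) ≈ 0.748`.

Net longwave radiation is bounded below at zero (no net longwave gain),
which also makes the degenerate zero-forcing day (no radiation, no wind,
saturated air, zero diurnal range) evaporate exactly nothing. Elevation
defaults to sea level and sets the psychrometric constant via pressure.

Growing degree days are `max(0, min(Tav, Tupper) − Tbase)` with Tbase
8 °C and Tupper 30 °C. "Not included" for temperatures above the upper
threshold is implemented as *capping* Tav at Tupper rather than
discarding the day: discarding whole warm days would undercount heat in
exactly the days that drive development, and capping is the standard
choice in water-driven crop models.

## Adaptive sowing and phenology

Sowing is the first day in the 1 March – 29 April window on which the
daily minimum temperature exceeded 8 °C on 4 consecutive days, that run
lying entirely inside the window and ending on (and including) the sowing
day; if no day qualifies, sowing is 29 April. Confining the qualifying
run to the window (rather than letting warm late-February days count) is
the conservative reading of "the last 4 days" — it never sows before
4 March — and is pinned by tests. The threshold is strict: a minimum of
exactly 8 °C does not qualify.

The crop cycle is defined in cumulative GDD counted from the day after
sowing: emergence at 80 °C·day, flowering 620, maximum canopy 673,
senescence 898, maturity 1122 °C·day. The 1122 total is the calibrated
cycle requirement of the generic cultivar; the sub-stage values are this
package's configuration, set to typical maize fractions of the total
(7%, 55%, 60%, 80%), since no authoritative sub-stage table was
available. A cell-year *completes* its cycle when cumulative GDD from
sowing to 31 December reaches 1122 °C·day, comparison inclusive at the
threshold ("enough" reads as attainment). Cycle *length* is counted in
calendar days from emergence (germination) to maturity, so completion is
tested from sowing while length is reported from germination — both
conventions are explicit in the code. Incomplete cycles report no length
and yield zero.

## The crop engine

The engine is a minimal AquaCrop-style water-driven core, not a port of
any full model: one root-zone bucket, no Richards equation, no
groundwater, no salinity or nutrient dynamics.

**Soil water.** The bucket spans the current rooting depth, which grows
from 0.3 m to the profile maximum (default 1.5 m) proportionally to
cumulative GDD up to the maximum-canopy threshold. Water entering the
zone as roots deepen (at the profile's initial moisture) is tracked as an
explicit influx term, so the seasonal balance
`precip + irrigation + deepening influx + Δstorage = transpiration +
evaporation + drainage` closes to well under 0.01 mm by construction —
and is asserted, not assumed, in the tests. Rain above saturation
overflows immediately; half of any remaining excess above field capacity
drains per day (a crude but adequate stand-in for gravity drainage that
keeps post-storm moisture near field capacity). Depletion below the
wilting point is impossible: extraction is capped at the
plant-available store.

**Stress coefficients.** With depletion Dr and total available water TAW
= (θfc − θwp)·z·1000, the stomatal coefficient Ks,sto is 1 while
Dr ≤ p_upper·TAW (default 0.5, the readily available water RAW) and falls
linearly to 0 at TAW; the expansion coefficient Ks,exp does the same from
p_lower·TAW (default 0.25) — expansion stress begins earlier than
stomatal stress, as in the underlying crop physiology.

**Canopy.** Cover grows logistically per GDD at rate `cgc` toward its
maximum and declines exponentially at `cdc` after senescence; growth is
scaled by Ks,exp. Transpiration is `Ks,sto · Kc,Tr,x · CC · ETo`
(Kc,Tr,x = 1.05 at full canopy); soil evaporation is
`ke_x · (1 − CC) · ETo` with a two-stage drying reduction bookkept on a
0.10 m surface layer (readily evaporable water, then a linear falloff to
the totally evaporable water).

**Biomass and yield.** Biomass accumulates as
`WP* · f_CO2 · f_wp,fert · Tr/ETo` with normalized water productivity
WP* = 33.7 g/m² — the water-driven core: growth is proportional to
transpiration relative to atmospheric demand. The CO2 factor is a
saturating, C4-muted curve `1 + 0.10·d/(|d| + 200)` with d the excess
over the 369.41 ppm reference, i.e. at most +10% at very high CO2 and
exactly 1 at the reference. The harvest index builds linearly in GDD from
flowering to maturity up to HI0 = 0.48, **each increment scaled by
Ks,sto**: water stress during yield formation reduces grain set. This
stress modulation is a deliberate design choice. With a purely linear
build, the total transpiration of a season is nearly conserved under
drought regardless of canopy size, and a fertility-stressed crop can
never out-yield an unstressed one — yet that inversion (negative YGw) is
a documented behaviour of water-driven models in water-limited
environments, and this package treats its reachability as a requirement.
Scaling the HI increments by stomatal stress supplies the missing
nonlinearity through the real agronomic channel (drought around flowering
devastates maize grain set) while leaving stress-free seasons untouched.

**Irrigation (Yp regime).** Net-requirement irrigation tops the root zone
back up to the trigger depletion (default 0.5·RAW) at the end of any day
that would exceed it — the exact depth, no application losses. The
maximum end-of-day depletion fraction is reported and never exceeds the
trigger.

## Fertility stress and its calibration

Bulk "soil fertility stress" (default 30%, i.e. relative biomass
production Brel = 70%) is decomposed over three factors: the maximum
canopy cover and the initial cover at emergence are both scaled by
`f_ccx_fert`, and normalized water productivity by `f_wp_fert`, with
weights 0.70 and 0.30 per unit stress intensity (a growth-rate factor
`f_cc_fert` exists in the interface but carries weight 0). A
one-dimensional root search finds the intensity at which a reference
no-water-stress season reproduces the target stressed/unstressed biomass
ratio within 0.5 percentage points.

Scaling *both* the initial and the maximum cover is the load-bearing
subtlety: a logistic with carrying capacity `f·CCx` started at `f·CC0` is
exactly the unstressed curve scaled pointwise by `f`, so under
non-limiting water the seasonal biomass ratio is `f_ccx·f_wp` regardless
of the weather trajectory — the calibrated Brel transfers exactly from
the calibration season to any other stress-free season. Reducing the
growth *rate* instead makes the ratio depend on how the season's days map
onto the GDD axis and was measured (during development, on batches of
generated seasons) to drift by up to ±0.7 percentage points, more than
the calibration tolerance itself. The canopy-dominant split also gives
the stressed crop a genuinely smaller transpiring canopy, which is what
makes Yw < Ya reachable under drought.

## Gap analysis and aggregation

Yield gaps are computed on multi-year *mean* yields (matching the
multiyear-average presentation of this kind of analysis), with per-year
series retained for variability views. Incomplete years are excluded from
means rather than zero-filled, but count as crop failures (yield below
4 ton/ha) — a year without harvestable grain is a failure even though it
carries no yield statistic; both behaviours are switchable. Water
productivity (kg grain per m³ of evapotranspired water,
`100·yield/ETc`) defaults to the ratio of mean yield to mean seasonal
ETc; a per-year-mean variant is available. Seasonal ETc runs from
germination to maturity.

Ensemble aggregation uses the per-cell *median* across members (robust
for 5-member ensembles). A cell enters the analysis only if every member
completes at least 5 crop cycles in the 30-year period; change maps are
crossmasked (baseline AND future), while single-scenario suitability maps
are not. Suitability thresholds are strict as worded: below 4 ton/ha is
unsuitable, above 7 profitable, the boundaries themselves fall in the
middle class. Spatial means are unweighted; quartiles use linear
interpolation between order statistics.

## Problem sizes and numerical choices

The package's standard experiment — and the one its end-to-end tests run —
is a 20-cell latitude gradient (38–55° N), 5 ensemble members, 30-year
baseline (1985–2014) and future (2030–2059, +2 °C, 5% drier, CO2 450 ppm
rising 3 ppm/yr) periods, three regimes: 18 000 simulated seasons,
completing in a couple of minutes on one CPU. The fertility root search
uses `uniroot` to 10⁻⁷ on the stress intensity and is memoised per
(crop, soil, target). Sub-seeds for every scenario/member/cell stream are
derived from the single global seed by a 31-bit linear congruential mix,
so partial re-runs reproduce exactly. Gridded outputs are written as tidy
long-format CSV plus a JSON run manifest (config hash, seed, periods).

## Known limitations

* The engine is deliberately minimal: no heat sterility at flowering, no
  pest/disease or extreme-event damage, no multi-layer soil, no
  groundwater or capillary rise, no curve-number runoff.
* The Yp regime is energy-limited by construction but shares the rainfed
  cultivar parameterization; treat its absolute level as indicative and
  its relative changes as the meaningful signal.
* Cells are statistically independent; domain summaries understate the
  spatial coherence real weather would induce.
* The generator's parameters are free knobs describing a plausible
  European climate, not estimates fitted to any reanalysis product.
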