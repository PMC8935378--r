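---
title: "Simulating nutrient-limited cassava growth: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating nutrient-limited cassava growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassavaNPK)
```

## The model in brief

cassavaNPK simulates one cassava season at a daily time step. Potential
growth is source-driven (radiation-use efficiency times Beer's-law light
interception); realized growth is the potential times the *stricter* of
two stress factors — the transpiration reduction factor `TRANRF` from a
tipping-bucket water balance and the combined nutrient stress index
`NPKI` — and is zero during drought-induced dormancy. The two-branch
published form of this law ("use `TRANRF` when `TRANRF ≤ NPKI`, else
`NPKI`") is implemented as the single expression
`min(TRANRF, NPKI)`, which is provably identical and is verified against
the piecewise form on a dense grid in the test suite.

Five nutrient processes run each day, in a fixed order: soil supply of
N, P and K; plant demand; uptake and allocation; redistribution between
organs; and stress. All rates are computed from start-of-day states and
integrated with an explicit Euler step of one day (`DELT = 1`), the
convention of this model family; this prevents order-dependent coupling
artifacts, and identical inputs give bit-identical output.

### Soil supply

Each nutrient has three pools: plant-available `A`, unreleased soil
supply `S` and unreleased fertilizer `F` (all g m⁻²). A quarter of the
season-total soil supply is available at emergence; the remainder
releases at a constant rate sized so the pool lasts 0.9 of the season
length. Fertilizer releases first-order at relative rate `rf` (0.1, 0.01
and 0.04 d⁻¹ for N, P and K), multiplied by the water-limitation factor
`WLIMIT = TRANRF/(K_WATER + TRANRF)`; only the fraction `Rec` (0.75, 0.28,
0.70) of what leaves `F` reaches `A`, so `Rec` is exactly the asymptotic
fertilizer recovery — the remainder is an implicit loss term. Two
formulation points were genuinely open and were resolved as follows:

* the published rate equation is typographically ambiguous about whether
  `WLIMIT` scales both release terms; here it scales the *fertilizer*
  term only, matching the prose ("reduces fertilizer release rates");
* no depletion law is published for `F`; first-order depletion at
  `rf·F·WLIMIT`, with the `(1 − Rec)` share lost, is the simplest law that
  reconciles the rate equation's product form with the "maximum recovery"
  meaning of `Rec`. The asymptote is verified to 1% in the tests.

A site's supply is parameterized from uptake measurements: base supply per
nutrient (control-plot uptake) plus an *extra* supply measured in omission
treatments (the additional uptake of the omitted nutrient when the other
two are applied). The extra is activated when the fertilizer schedule
applies a nonzero amount of both other nutrients — a binary rule, because
the measurements are treatment-specific and no dose–response for partial
rates is published; a 0–1 `extra_scale` override is exposed for users who
prefer the proportionality hypothesis. A negative measured extra (it
happens: the potassium extra on the calibration site is negative) clamps
to zero with a warning, since supply pools cannot be negative.

### Demand, nutrient equivalents and uptake

Whole-plant minimum and maximum nutrient amounts are concentration ×
weight sums over the four living organs, with min/max concentrations read
from thermal-time lookup curves (linear interpolation, constant beyond the
ends). Demand and soil supply are converted into *nutrient equivalents*:
relative P and K deficits (or pools) are scaled by the maximum N amount,
making the three nutrients commensurate. Total equivalent uptake is capped
at `RNE · min(NES, NED)` with `RNE = 0.012 d⁻¹`, and each nutrient's
uptake is additionally bounded by its own unmet demand and by its
available pool (uptake is bounded by `A` *after* the day's release, since
release precedes uptake in the daily ordering). Uptake is allocated to
organs proportionally to biomass.

This coupling is the scientific heart of the model: a potassium shortage
inflates the equivalent demand and thereby accelerates N and P uptake,
while simultaneously limiting total equivalent uptake — so cumulative N
uptake falls when K is scarce, which the tests check as a property.

### Redistribution and rerouting

Organs are pushed toward equal relative nutrient saturation (the model
family's assumption that all organs sit at the same relative distance
between their minimum and maximum concentrations). "Proportional demand of
the organ" is operationalized as the whole-plant actual amount shared in
proportion to each organ's contribution to the whole-plant maximum — the
reading that achieves equal relative saturation at steady state. Transfers
relax toward that target at 1/`TC_NPK_T` = 0.1 d⁻¹; the published time
coefficient (10 d) and relative rate (0.1 d⁻¹) are numerically the same
mechanism and are treated as one parameter. Redistribution sums to zero
per nutrient and never affects growth directly.

Dying leaves carry no nutrients into the dead pool: their N moves to the
stems and their P and K to the storage roots. Within-season recycling of
fallen-leaf nutrients through the soil is deliberately not modelled (net
loss set to zero). After a dormancy spell ends, a configured fraction of
storage-root biomass converts to new leaf biomass with an NPK transfer
proportional to the biomass decrement, conserving whole-plant totals.

### Stress

Per nutrient, the nutrition index is `NI = (Act − Min)/(Opt − Min)`,
clamped to [0, 1] (luxury uptake above the optimum is allowed transiently
but saturates the index), with `Opt = Min + FR_MAX·(Max − Min)`,
`FR_MAX = 0.8`. The three indices multiply, and the product π passes
through a saturating transform with `c = K_NI + 1`:

* `NPKI = c·π/(K_NI + π)` when `K_NI ≤ KMAX`;
* `NPKI = 1 − c·(1 − π)/(K_NI + (1 − π))` when `K_NI > KMAX`.

Both branches return exactly 1 at π = 1 for any `K_NI`; with the
calibrated `K_NI = 6.1 > KMAX = 4` the complement branch is active and
π = 0.8 gives `NPKI = 0.77` — joint limitations are penalized more than
the product alone. Before `TSUM_NPKI = 272 °C·d` the index is forced to 1:
the young plant runs on cutting reserves, and the early-season indices are
genuinely below optimum even under generous supply (see *Limitations*), so
growth is not reduced there. Nutrient stress also accelerates leaf death
(`RDRNS = 0.05 d⁻¹` at full stress), combined with background and drought
senescence by maximum rather than addition to avoid double counting, and
deepens fine-root partitioning through the same hook drought uses.

## Parameters and their defaults

The nutrient block (`RDRNS`, `TSUM_NPKI`, `FR_MAX`, `Rec_*`, `rf_*`,
`TC_NPK_T`, `K_NI`, `KMAX`, `K_WATER`, `RNE`) carries the published
constants of the model family and is validated on load (`FR_MAX`,
recoveries in [0, 1]; positive Monod constants; `DELT = 1`).

The base-crop block (RUE 2.8 g DM MJ⁻¹, extinction 0.7, SLA
0.015 m² g⁻¹, base temperature 16 °C, sprouting at 150 °C·d, the
partitioning table) and the soil-water block (field capacity 0.32,
wilting point 0.15, saturation 0.45, air-dry 0.05 by volume; rooting to
3.2 m at 0.02 m d⁻¹; transpiration coefficient 8 mm d⁻¹) describe the
underlying water-limited model, which is published elsewhere; the values
here are stand-ins in the physiological range for cassava in the humid
tropics and should be overridden from a configuration file for
site-specific work. The same caveat applies with emphasis to the organ
min/max concentration curves: the measured curves live in unpublished
supplementary material, so `defaultConcentrationTable()` is a clearly
flagged synthetic stand-in — monotonically diluting with thermal time,
anchored so that season-scale maximum amounts sit near measured uptakes of
well-fertilized crops (≈45 g N, 5 g P, 30 g K m⁻² at a 3.5 kg DM m⁻²
canopy-plus-roots) and minima at roughly 30% of maxima. Fine roots inherit
the stem curves, as no separate curves are published. Users with measured
curves load them via `readConcentrationTable()`.

All internal arithmetic is in g m⁻² and g g⁻¹ DM; kg ha⁻¹ is accepted
only at the I/O boundary (an exact ÷10).

## The synthetic weather generator

`syntheticWeather()` emulates a southern-Nigeria season starting at the
onset of rains: tmin ≈ 21–23 °C, tmax ≈ 29–33 °C, 8–24 MJ m⁻² d⁻¹ global
radiation, and a wet-day/gamma-intensity rain process whose probability
and intensity drop in the mid-season dry period (days 160–280 after a May
planting). The `wet` profile represents an abundant ~3000 mm year (total
rain over 420 days stays above 2000 mm; the water balance then reports
`TRANRF = 1` on at least 95% of days, matching a no-drought season), and
the `dry-spell` profile imposes a hard ~90-day mid-season drought for
dormancy studies. The generator is seeded and side-effect-free on the
caller's RNG.

What it does *not* emulate: multi-year weather sequences, cyclones and
storm clustering, station-specific radiation/temperature correlations, or
real-site soil heterogeneity. Passing tests on this generator therefore
demonstrates internal consistency and qualitative response patterns —
treatment orderings, stress dynamics, mass balance — not predictive skill
against field data, which requires site weather and measured
concentration curves.

## Calibration and evaluation

`calibrateNPKI()` estimates (`K_NI`, `KMAX`, `TSUM_NPKI`) by minimizing
the sum over observation variables (storage-root DM and N, P, K uptakes
at roughly 4, 8 and 14 months) of RMSE normalized by each variable's
observed mean — the published procedure optimizes jointly over these
variables without stating weights, and mean-normalization is the neutral
way to make g-of-root and g-of-nutrient errors commensurate. The search is
a coarse deterministic grid (steps of 1, 1 and 50 by default) followed by
Nelder-Mead refinement clamped to the bounds; the reported optimum is the
best point ever evaluated, with exact ties broken toward the
lexicographically smallest triple, so the whole procedure is reproducible.
`evaluateSim()` reports RMSEP, R² and the slope of simulated regressed on
observed (slope ≈ 1 ⇒ unbiased; the published description does not fix the
regression orientation, and R² is orientation-free).

Two identifiability facts deserve emphasis. First, `KMAX` enters the model
*only* through the branch condition `K_NI ≤ KMAX`: data generated in one
branch constrain it only through that inequality, the objective is exactly
flat in `KMAX` within a branch, and the tie-break therefore returns the
lower search bound (the default bounds start at the published value 4).
Recovery experiments genuinely test `K_NI` and `TSUM_NPKI`; `KMAX` should
be regarded as set by convention, not estimated, whenever `K_NI > KMAX`.
Second, `TSUM_NPKI` only acts through which whole days are gated, so the
objective is piecewise-constant in it with steps the size of a daily
thermal increment (~10 °C·d); recovery to ±25 °C·d is the attainable
resolution. With zero-noise synthetic observations from two treatments of
a 420-day season, the harness recovers (6.1, 4 ± 0.5, 272 ± 12).

Synthetic observations add mean-one multiplicative lognormal noise at a
chosen CV — multiplicative because yield and uptake errors scale with
magnitude, mean-one so calibration targets stay unbiased.

## Numerical choices and degenerate inputs

* Equivalent-demand and supply terms with a zero maximum amount evaluate
  to 0 (no biomass yet — avoids 0/0 at emergence); uptake is 0 until the
  crop sprouts.
* `NI` with `Opt = Min` degenerates to 1 at or above the minimum, else 0.
* Total equivalent demand is floored at 0; per-nutrient uptake rates are
  floored at 0 (actual amounts can transiently exceed maxima when leaf
  death shifts nutrients into smaller organs).
* The water bucket never extracts below air-dry; transpiration plus
  evaporation are rescaled jointly if they would. Newly rooted soil enters
  at field capacity (a humid-tropics assumption), and the daily balance
  closes exactly including that term.
* Nutrient amounts are guarded against negativity: values below −1e−9
  abort the run naming the day and pool; tiny negative rounding residues
  clamp to 0. Mass-balance tests hold to 1e−8 g m⁻² per season (observed
  closure ~1e−13).
* `TRANRF` is 1 when potential transpiration is 0 (no demand ⇒ no
  stress); a per-day `TRANRF` override is a bit-exact pass-through that
  bypasses the bucket.

## Problem sizes

The shipped tests and recovery harness use 420-day seasons (the 14-month
cropping cycle) at a daily step, 5-treatment omission batteries, and a
9×5×8 calibration grid plus ≤200 simplex evaluations — sizes chosen so a
single season simulates in well under a second and the full recovery
experiment in a few minutes on one core, which is the scale at which this
class of model is routinely run and re-run during calibration.

## Known limitations

* Early-season nutrition indices fall below 1 even with saturating soil
  pools: demand-limited equivalent uptake closes at most ~3·`RNE` of the
  relative deficit per day, which cannot track the canopy-establishment
  phase where demand grows at 5–15% per day. This is a structural property
  of the uptake equations — it is why the `TSUM_NPKI` gate exists, and
  published simulations of this model family show the same early
  sub-optimal indices. Consequently a "sufficiency" run that must be
  bit-identical to the nutrient-free baseline needs *all* nutrient pools
  saturated, including the cutting reserve (which supplies new growth at
  maximum concentration outside the soil-uptake kinetics); soil pools
  alone leave a genuine early stress signal.
* Nutrient limitation does not alter shoot partitioning (only the
  fine-root share) and does not touch RUE directly; severe-imbalance
  effects on harvest index are therefore outside scope, as in the parent
  model.
* No leaching, sorption, mineralization dynamics or litter feedback; soil
  supply is an empirical, measurement-derived input.
* One soil layer, no runoff routing or capillary rise, no VPD-stomatal
  response; the water module exists to provide the `TRANRF`/`WLIMIT`
  contract and the dormancy trigger, not as a hydrology model.
* Default base-crop parameters and concentration curves are stand-ins (see
  above); quantitative site work must override them. Reproducing published
  field-accuracy statistics is not possible from this package alone, as it
  requires the unreleased plot observations and station weather.
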