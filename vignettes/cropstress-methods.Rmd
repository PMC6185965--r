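---
title: "Methods: a switchable-stress crop simulator and its factorial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a switchable-stress crop simulator and its factorial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropstress)
library(dplyr)
```

## What the package computes

Warming affects cereal yields through separable mechanisms: it accelerates
development (shorter seasons, lower potential yield), it raises vapor pressure
deficit (VPD) and hence water demand (deeper drought), and it pushes
temperatures over reproductive damage thresholds (heat stress) — with drought
and heat coupled through canopy temperature, because a water-stressed canopy
stops transpiring and heats above the air while a fully transpiring one cools
below it. `cropstress` isolates these drivers with a six-treatment factorial
run on synthetic but statistically controlled inputs:

| treatment | water limitation | heat stress driver |
|---|---|---|
| T1 | off (full irrigation) | none |
| T2 | off | air temperature |
| T3 | off | canopy temperature |
| T4 | on | none |
| T5 | on | air temperature |
| T6 | on | canopy temperature |

T1 yields are potential (`Yp`), T4 water-limited (`Ywl`), T2/T3 heat-limited
(`Yhl`), T5/T6 combined (`Ywh`). Every scenario is simulated twice — ambient
CO₂ fixed at 360 ppm and the pathway's elevated level (442, 499 or 571 ppm) —
so CO₂ fertilization is a separable on/off factor.

## The crop simulator

The daily loop is deliberately minimal: each mechanism is the simplest form
that produces the right qualitative coupling, so that every treatment contrast
is attributable to exactly one switch.

* **Phenology.** Thermal time accumulates as
  `min(max(tavg, t_base), t_opt) − t_base`; anthesis and maturity occur at
  fixed thermal-time targets. This is what makes warming mature the crop
  earlier and is the entire "mean temperature" driver of potential yields,
  together with a trapezoidal temperature suitability on growth (linear from
  `t_base` to `t_opt`, declining to zero at `t_max`).
* **Growth.** Leaf area rises with thermal time to a maximum at anthesis and
  declines linearly to zero at maturity; interception is
  `1 − exp(−k·LAI)`; potential growth is RUE × intercepted radiation ×
  temperature suitability.
* **Water.** Demand converts potential growth through a
  transpiration-efficiency relation `demand = growth · VPD / (TE_c · te_mult)`
  — linear in VPD, which is where the non-linear temperature→demand link
  enters (VPD uses the Tetens saturation curve at tmax/tmin). A single-layer
  bucket supplies at most the fraction `kr = 0.1` of its store per day;
  `f_w = supply/demand` multiplies growth. Under irrigation the supply is
  topped up so `f_w ≡ 1` exactly. Water is conserved to machine precision on
  every trajectory; this is asserted, not assumed. Soil evaporation is
  omitted: the bucket tracks transpiration only, which preserves the drought
  signal while keeping the balance trivially auditable.
* **Heat.** Daily exceedance of the driver temperature above `t_crit` (31 °C
  wheat, 35 °C maize) inside a thermal-time window around anthesis accumulates
  into a harvest-index retention `max(0, 1 − slope·Σ exceedance)` — a
  grain-number proxy for irreversible reproductive damage. The driver is tmax
  (air mode) or `tmax + δ_heat(1−f_w) − δ_cool f_w` (canopy mode, defaults
  δ_heat = 5 °C, δ_cool = 2 °C). Under irrigation the canopy is therefore
  always cooler than the air (T3 ≥ T2); under drought it is hotter whenever
  `f_w < δ_heat/(δ_heat+δ_cool)`, which is the drought × heat interaction.
* **CO₂.** Multipliers `1 + coef · ln(CO₂/360)`: transpiration efficiency for
  both classes (γ_TE = 0.35 wheat, 0.25 maize), plus RUE (β_RUE = 0.20) and
  leaf area (λ_LAI = 0.06) for the C3 crop only. C4 potential yields are
  exactly invariant to CO₂ by construction. The coefficient sizes give a
  ≈ +9–12% C3 assimilation-side response at 571 ppm, in the range reported by
  free-air enrichment experiments; they satisfy β_RUE + λ_LAI < γ_TE, which
  makes daily water demand non-increasing in CO₂ and hence water-limited
  yields provably non-decreasing — the contract the test suite asserts.

**Accelerated senescence.** A configurable `senescence_threshold` terminates
leaf-area growth once cumulative heat exceedance passes it. The shipped
presets set it to `Inf`: when active, the senescence–water feedback (less leaf
→ less demand → more stored water later) can in principle let a heat-stressed
run out-grow its no-heat counterpart in rare cells, which would break the
strict treatment ordering Y(T4) ≥ Y(T6) that the rest of the analysis relies
on. With the default off, heat acts through harvest-index retention alone and
the ordering is exact. The mechanism itself is covered by a test with a finite
threshold.

**Winter cereals.** Vernalization and photoperiod are not modeled; the autumn
sowing date (day 289) with a 0 °C base temperature reproduces the key
contrast — wheat grows through the cool season and matures in early summer,
largely escaping peak drought and heat, while maize (sown day 115, base 8 °C)
sits in mid-summer.

## Synthetic inputs: what they emulate, and what they do not

The generators stand in for gridded climate, soil and land-use databases, and
for national yield statistics.

* **Weather**: harmonic seasonal cycle + AR(1) daily residuals for
  temperature (the harmonic sums to zero over whole 365-day years, so the
  configured annual mean is also the closed-form expectation — used directly
  in tests); Bernoulli-gamma rainfall (wet day := precip ≥ 0.1 mm, the
  operational wet/dry definition); harmonic radiation dimmed 10% on wet days;
  humidity as a fixed fraction (0.85) of saturation vapor pressure at tmin
  (dewpoint ≈ tmin), keeping VPD non-negative; no leap days. Three latitude
  bands (boreal, temperate, mediterranean — the latter with dry summers) span
  the drought gradient. Real weather's spatial correlation between cells,
  inter-annual persistence, and radiation–temperature covariance are *not*
  emulated, so passing tests say nothing about reproducing any particular
  region's observed statistics — only about the internal consistency of the
  method.
* **Scenarios** follow the delta-change idea: monthly mean offsets and
  precipitation factors, explicit wet↔dry flip plans (radiation ±10% on
  flipped days), and the pathway CO₂ level. Higher-moment variability changes
  are out of scope; flip days are sampled at configured rates because no
  mapping from frequency change to specific days is defined — the plans are
  explicit inputs, not inferences.
* **Soils**: depth and per-cm available water are drawn per cell;
  `FC = WP + TAWC/(10·depth)` (mm/cm unit convention); profiles shallower than
  40 cm are rejected and redrawn (count logged). Initial water is 30%
  depletion of readily available water, with RAW = 0.5 × TAWC — the standard
  depletion fraction, exposed as `raw_fraction` since "readily available" is
  otherwise underdefined.
* **Observed yields** are simulated truth + linear technology trend +
  Gaussian noise, with the generating metadata retained so evaluation tests
  can assert recovery.

## The analysis stages

* **Aggregation** is production-weighted: unit yield = Σ yield·area / Σ area,
  with rainfed, irrigated, total, or mixed weights (the mix pairs each
  water-limited treatment with its irrigated counterpart, T4–T1, T5–T2,
  T6–T3). Weights are always baseline areas; no land-use change. The
  environment index (water-limited / potential yield) weights both sides by
  rainfed areas so it is exactly 1 wherever drought never binds, regardless of
  how areas are distributed.
* **Decomposition** computes losses from multi-year mean yields per (unit,
  model, GCM-analogue, scenario, CO₂ arm) — not as means of annual ratios,
  which would be unstable when annual potential varies; the alternative is a
  deliberate non-feature. Members without a canopy-temperature routine fall
  back to the air-temperature treatments. The lowest decile is the
  ⌈n/10⌉ smallest-yield years (ties to earlier years) of the fully limited
  treatment of the same CO₂ arm, selected per model rather than on the
  ensemble median — a documented choice where either reading is defensible.
  Drought loss + rainfed heat loss ≡ combined loss algebraically; the suite
  asserts it at 1e-9 on every row. Ensemble summaries are medians with
  10th/90th percentiles across model × GCM-analogue combinations.
* **Evaluation** de-trends observed and simulated series identically with a
  centered 5-year moving mean, 3-year windows at the second and penultimate
  years, and the two available years at the extremes (a centered window does
  not exist there; the truncated window loses no years and is covered by
  tests). Centered windows annihilate linear trends at interior points.
  Anomalies are absolute by default (`relative = TRUE` available), a linear
  de-trend is provided as the alternative, and significance uses α = 0.05 —
  all three choices surfaced as arguments because no single convention is
  canonical. Skill is squared Pearson correlation; a negative correlation is
  flagged rather than silently squared away.
* **Uncertainty decomposition** uses main/total-effect indices with
  *population* variances (÷N), so on balanced finite factorials the classical
  identities are exact (additive ⇒ ΣME = 1 and TS = ME; pure interaction ⇒
  ME = 0, TS = 1) rather than approximate — the test suite checks equality to
  an independent brute-force oracle at 1e-12. Replicates (cells × years)
  collapse to factor-cell means by default, matching a design whose response
  is the aggregate yield per factor combination; `collapse_replicates = FALSE`
  keeps replicate noise in var(Y) for noise-inclusive recovery studies. When a
  pathway lacks some climate-model analogues the default policy restricts to
  the analogues present everywhere (announced loudly); erroring is the
  alternative.

## Problem sizes and reproducibility

The shipped stylized-Europe configuration uses 6 regions over 3 latitude
bands, 60 cells, 30 harvest years, baseline + 2 pathway analogues × 2
climate-model analogues, 4 pseudo-models and both crop presets — 864,000
simulated seasons — which keeps a full pipeline run in the minutes range on a
single core; the test suite uses the same scale for the factorial contracts
and smaller grids elsewhere. Every random draw descends from one base seed via
a deterministic string-keyed stream splitter (`mix_seed()`), rows of the
factorial are mutually independent, and reruns are bit-identical — the
acceptance script verifies this by running the pipeline twice and comparing
output bytes.

The pseudo-ensemble jitters RUE, TE, thermal times (one shared factor, so
anthesis < maturity survives), heat slope, and the CO₂ coefficients (one
shared factor, so β_RUE + λ_LAI < γ_TE survives) log-normally around the base
parameterization; member 1 is always the unperturbed base. This emulates
between-model spread, not structural diversity: all members share one model
form, which is the main caveat when reading ensemble percentiles.

## Known limitations

No nitrogen, pests, disease, lodging or water-logging; no soil evaporation or
runoff; no vernalization/photoperiod; one-layer soil water; heat damage only
via harvest index (plus the optional senescence switch); weather cells are
statistically independent; the "observed" series share the simulator's own
structure, so evaluation demonstrates methodological self-consistency, not
real-world skill.
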