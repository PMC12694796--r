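---
title: "Heritage microclimate risk: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritage microclimate risk: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmrisk)
```

## The model

`hmrisk` scores how far monitored indoor conditions deviate from
conservation and health standards. Two index families share one structure:

* **HMR_E** (exhibit conservation) uses indicators whose standard is an
  acceptability *range* — temperature, relative humidity, artificial light.
  Its scale is two-sided: −1 means conditions at (or beyond) the lower limit
  (a *deficit*, e.g. light too dim or air too dry), +1 at the upper limit
  (an *excess*), 0 optimal.
* **HMR_H** (human health) uses indicators whose standard is a one-sided
  *threshold* — CO₂, HCHO, TVOC, PM₂.₅, PM₁₀, and the two air-ion
  concentrations. These cannot harm by being "too good", so the scale is
  one-sided on [0, 1].

Each indicator contributes two components. The *mean-level* component asks
where the period mean sits relative to the standard; the *oscillation*
component asks how large the day-to-day, same-hour fluctuations are. Large
fluctuations stress hygroscopic materials even when the mean is compliant,
which is why the two components are kept separate and only combined at the
end as their arithmetic mean. Room scores are unweighted means over
indicators, the overall score an unweighted mean over rooms; every
aggregation step is exact arithmetic, deliberately free of weighting
choices that would be hard to justify from monitoring data alone.

### Mean-level component

For a range `(lo, hi)`, optionally widened multiplicatively by the fraction
of oscillation the standard tolerates (`hi · (1 + f)`, `lo · (1 − f)`;
`f = 0` by default, keeping the published limits authoritative):

$$\mathrm{HMR}_{env} = 1 - 2\,\frac{hi - \bar x}{hi - lo},$$

clamped to [−1, 1]. This is affine in the mean: −1 at `lo`, 0 at the
midpoint, +1 at `hi`. Note the formula scores the *mean's position in the
range*, not compliance as such; a mean at the upper limit scores +1 even if
no single hour exceeds it. An alternative `exceedance_only` mode scores 0
for any mean inside the range and, outside it, grows with both the
excursion magnitude and the fraction of out-of-bounds hours; it is selected
per run (`range_mode = "exceedance_only"`), with the linear map as the
default because it is the more widely used form of this index family.

For a threshold `P_opt` the default *semantic* score blends frequency and
magnitude of exceedance:

$$\mathrm{HMR}_{env} = \tfrac12 E_{mag} + \tfrac12 E_{freq}, \qquad
  E_{mag} = \mathrm{clamp}\!\left(\frac{\bar x - P_{opt}}{P_{sat} - P_{opt}},\,0,\,1\right),$$

where `E_freq` is the fraction of hours beyond the threshold and `P_sat` is
a saturation level at which the magnitude term maxes out. The score is
exactly 0 when no observation exceeds the threshold, and monotone
non-decreasing in both terms — the properties a one-sided exposure index
must have. The magnitude weight (`alpha = 0.5`) treats "how far" and "how
often" as equally informative; it is a tunable argument, not a constant.

A *verbatim* linear form, `1 − 2(\bar x − P_{opt})/(P_{sat} − P_{opt})`
clamped to [0, 1] (0 outright for sub-threshold means), is retained behind
`threshold_mode = "verbatim"` for auditability against legacy spreadsheet
implementations of this index family. Its gradient runs opposite to the
semantic scale — it scores *highest* for means just past the threshold —
so it is not the default.

For the one lower-threshold indicator (negative ions, which should stay
*above* 1000 ions/cm³) the axis is mirrored: risk is the deficit below the
limit, `E_mag = clamp((P_opt − \bar x)/(P_opt − P_{sat}), 0, 1)` with
`P_sat < P_opt`.

### Oscillation component

The raw statistic pairs each hour with the same hour one calendar day
later:

$$\Delta M = \sum_{k}\sum_{j=0}^{23} \left|X_{day\,k,\,hour\,j} - X_{day\,k+1,\,hour\,j}\right|.$$

The absolute value is essential: a signed sum would telescope toward
cancellation and could not measure fluctuation magnitude. Pairs with a
missing value on either side are skipped, never imputed, and the mean
oscillation divides by the number of differences actually summed — not by
the number of hourly observations — so gaps do not dilute the statistic.

Range indicators score the mean oscillation linearly against an allowed
daily-oscillation band `(Δosc_low, Δosc_high)`, same anchors as the
mean-level map (−1 at the band floor, +1 at the ceiling, clamped).
Threshold indicators locate the mean variation between a safe floor
`ΔP_opt` and the worst observed variation `ΔP_max`:
`clamp((ΔP_mean − ΔP_opt)/(ΔP_max − ΔP_opt), 0, 1)`, defined as 0 when
`ΔP_max ≤ ΔP_opt` (no variation beyond the floor), which also removes the
division-by-zero case.

### Risk bands

Scores are banded on absolute value: below 0.2 *low*, 0.2–0.6 *moderate*,
0.6 and above *high*; conservation-index scores additionally carry an
excess/deficit direction. The cut-points are arguments (`cuts = c(0.2,
0.6)`) — they are anchors of the conventional reporting scale for this
index family, not estimated quantities.

## The standards registry

The packaged registry (`default_standards()`) carries the internationally
recommended limits: T 16–24 °C, RH 45–60 %, AL 50–200 lux, CO₂ ≤ 1000 ppm,
HCHO ≤ 0.04 mg/m³, TVOC ≤ 1 mg/m³, PM₂.₅ and PM₁₀ ≤ 35 µg/m³, I⁺ ≤ 1000
and I⁻ ≥ 1000 ions/cm³. Three groups of parameters are package defaults
because the standards bodies publish no single number for them:

* **Daily-oscillation bands.** T uses 1–2 °C/day (the tolerance band its
  standard attaches to the set-point), RH 3–10 %/day (from the ±3 %
  short-term tolerance up to a level conservators treat as clearly
  stressful), AL 10–50 lux/day; the pollutant floors (`ΔP_opt`) are set at
  roughly 5 % of each threshold. All are plainly visible in the YAML
  document and meant to be tuned per collection.
* **Saturation levels.** `P_sat` defaults to twice the threshold (half, for
  the lower-threshold indicator): at double the permitted concentration the
  magnitude term should be saturated. Overridable per indicator.
* **`osc_fraction` defaults to 0**: the published limits are used bare. The
  multiplicative widening is available per indicator for standards that
  phrase their tolerance as a percentage.

## The synthetic generator

`simulate_series()` produces hourly values as

`baseline + A·sin(2π(hour − φ)/24) + drift·day + AR(1) + pulses`.

The AR(1) term (default φ = 0.8) reflects that hourly indoor readings are
strongly autocorrelated — white noise would understate day-to-day
oscillation relative to hour-to-hour variance. Exceedance events are
additive boxcar pulses with independent rate, magnitude and duration: the
simplest structure that separately drives the frequency and magnitude terms
of the semantic score. Because pulse starts are drawn by thinning a fixed
uniform sequence, campaigns with the same seed and increasing rate have
*nested* pulse sets, which makes monotonicity of the score in the pulse
rate testable deterministically.

The demonstration campaign (`demo_campaign()`) emulates an eight-month
hourly campaign in two exhibition halls of an HVAC-only museum: temperature
near 19–20 °C, relative humidity running above its 60 % limit, formaldehyde
frequently above 0.04 mg/m³, positive ions oversaturated, the remaining
pollutants compliant. What the generator does **not** emulate: coupling
between indicators (RH tracking T through HVAC cycles), regime changes
(season-dependent visitor load), sensor drift or calibration error, or
heavy-tailed pollution episodes. Passing tests on synthetic data therefore
demonstrate that the *scoring machinery* is correct and stable — not that
any particular real building is safe.

## Colony-count quantitation

`CFU/g = NCC × DF / VP` with the assay constants DF = 50 (a 1:50 dilution)
and VP = 1 mL. Two censoring conventions are modelled rather than
discarded: a plate with no countable colony is a *below-detection* report
(stored with its conventional "< 10" reporting limit — note that with
DF = 50 a single colony already implies 50 CFU/g, so "< 10" is an assay
reporting convention, not Eq-arithmetic output), and confluent growth above
the countability ceiling (default 300 colonies/plate, the standard
plate-count convention) is *right-censored*. Treated-versus-untreated
comparisons propagate these bounds: a right-censored untreated plate
against a left-censored treated plate is an ordering that censoring itself
makes certain; two left-censored plates are an indeterminate fold change,
flagged *stable-low*. The mean-based log₁₀-reduction estimator enters
censored plates at their bounding counts (0 and the ceiling), making it
conservative under heavy censoring; the simulation tests run in a regime
where censoring is negligible.

## Numerical choices

* All scores are clamped to their scale after evaluation; the linear maps
  are otherwise unbounded when data leave the normalisation interval.
* Internal arithmetic is full double precision; report tables round half
  *away from zero* at 2 decimals (the convention of this reporting format),
  via `round_half_up()`.
* The oscillation sum is accumulated in its defining order (day pairs
  outer, hours inner), so it is bit-reproducible against an independent
  nested-loop implementation.
* Degenerate inputs fail loudly (empty series, inverted ranges, equal
  oscillation bounds) except where a convention exists: zero variation
  beyond the safe floor scores 0.
* Determinism: identical inputs and configuration produce byte-identical
  artifacts; report files contain no timestamps.

## Problem sizes in the test-suite

The suite exercises the oscillation statistic against a brute-force oracle
on 100 random series of up to 30 days; parameter-recovery runs use 30-day
campaigns; the log-reduction recovery uses 200 samples (400 plates per
arm), for which the delta-method Monte-Carlo standard error of the
estimator is ≈ 0.007 log₁₀ units. The acceptance script assesses the full
240-day demonstration campaign. These sizes give stable statistics while
keeping the default check fast on a laptop.

## Known limitations

* Component scores depend on the registry's oscillation bands and
  saturation levels; two sites using different defaults will produce
  different absolute scores. Publish the registry document alongside any
  reported index.
* The unweighted indicator average treats a light excess and a humidity
  excess as equally harmful, which materials science does not support; the
  index is a screening statistic, not a degradation model, and combined
  multi-factor degradation effects are out of scope.
* Cross-sensor aggregation is an unweighted per-timestamp mean, appropriate
  when sensors are distributed evenly; it has no notion of spatial
  representativeness.
* The health index quantifies exceedance of guideline values, not dose —
  no exposure-duration or dose-response modelling is attempted.
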