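---
title: "Models and methods behind swampdendro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swampdendro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swampdendro)
```

This vignette is the package's own account of the statistical machinery
it implements: the standardization model, the correlation-function and
growth-geometry analyses, the carbon-isotope chain, the synthetic-data
generator that stands in for field data, and the numerical and design
choices made where the methodology left room. It states no empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## Ring-width standardization

A measured ring-width series mixes three signals: an ontogenetic trend
(wide juvenile rings decaying toward a mature asymptote), a shared
interannual environmental signal, and tree-level noise. Standardization
removes the first so the second can be averaged across trees.

**Age-dependent smoother.** The ontogenetic curve `g(age)` is fitted
with a smoother whose stiffness grows with cambial age: the 50%
frequency-response wavelength at age *t* is `max(s0, t)` with
`s0 = 20` years by default, so the curve can follow the steep juvenile
decay but becomes nearly rigid in old age. Internally this is a
tricube-weighted local quadratic regression whose kernel half-width is
*half* that wavelength. The factor of two is the standard conversion
between a smoother's frequency-domain cutoff and its kernel scale; we
verified the choice on the package's own calibration case — a pure
negative exponential `w(t) = 3 e^{-t/40} + 0.3` detrends to
`max |RWI - 1| ≈ 0.006`, whereas using the full wavelength as the
half-width lets the old-age window reach back into the juvenile slope
and inflates the error to ~18%. Local polynomials reproduce constants
and straight lines exactly, which gives the trivial invariants (constant
series → RWI ≡ 1) for free. Fitted values are floored at
`floor_epsilon = 0.001` mm before division so absent rings and near-zero
fits cannot blow up the index; floored years are reported.

**Ratio index and prewhitening.** `RWI_t = w_t / g(age_t)`; absent
rings (width 0) give RWI 0 rather than missing, which keeps the sample
depth bookkeeping simple and is conservative. Each index is then
prewhitened with an AR(p) model, p chosen by AIC over 0..10
(Yule–Walker), and the innovations re-centred to mean 1. AIC is the
textbook criterion here but is deliberately permissive: on pure white
noise it keeps order 0 in only ~72–75% of replicates (the other 25%
pick a small spurious order), which is the expected behaviour of the
criterion, not an implementation defect; the test suite asserts a
majority bound rather than a fantasy 100%.

**Robust averaging.** The chronology value for a year is the Tukey
biweight mean (tuning constant `c = 9` on the MAD scale, iterated to
1e-8) of the contributing series' indices; when the MAD collapses the
median is returned. The biweight's estimating-equation root is used as
an independent oracle in the tests. Years with sample depth < 2 are
flagged — they carry a single tree's noise.

## Chronology quality

Mean sensitivity is computed per series on the detrended index (as
crossdating programs do on filtered series; a switch allows raw widths)
and averaged. The series intercorrelation `r̄` correlates each series
with the biweight master built from all *other* series over ≥ 10 common
years — the leave-one-out master avoids the self-correlation inflation
of a grand mean that contains the series itself. EPS follows as
`n r̄ / (n r̄ + 1 − r̄)`, clipped to [0, 1] with a warning when
`r̄ ≤ 0` (a chronology with no shared signal).

## Climate–growth correlation functions

For each monthly variable the analysis screens 28 windows: the 12
months of the previous year, the 12 of the current year, and
winter (Jan–Mar) and summer (Jun–Sep) seasons of both years —
precipitation is summed over a season, temperatures, VPD and water
depth are averaged. The chronology/environment overlap is truncated per
variable (a 32-year gauge record against a 219-year chronology uses the
31 years where both the current and previous calendar year are on
record); windows with more than 20% missing entries are dropped.

Significance uses the stationary bootstrap: years are resampled jointly
in geometric blocks of mean length `⌈n^{1/3}⌉` (circular wrap), the
correlation is recomputed `n_boot` times, and the 2.5/97.5 percentiles
form the interval. Two caveats are documented deliberately:

* **Percentile intervals are mildly liberal at these sample sizes.**
  Our own calibration measurement (thousands of seeded independence-null
  replicates at n = 100, plus cross-checks with `boot::tsboot`'s
  geometric-block resampler and a plain pairs bootstrap, which read the
  same or higher) puts the realized false-positive rate near 0.07–0.08
  rather than the nominal 0.05. This is a property of percentile
  bootstrap intervals for a correlation at n ≈ 100, shared with the
  field's standard tooling, not of this implementation.
* **No multiplicity correction** is applied across the 28 windows per
  variable, matching field practice; isolated significant cells are
  expected by chance and the print method says so.

## Basal area increment and age-class isolation

`BAI_t = π(r_t² − r_{t−1}²)` with `r_t` the cumulative radius; the
arithmetic is exact, so total area telescopes to `π (Σw)²` (asserted to
1e-9 relative over a thousand random series). A series missing rings to
the pith seeds `r_0` as `pith_offset × mean(first five widths)` unless
an explicit radius is given; the default pith offset is 0.

Age-class isolation compares same-aged trees across calendar time:
5-year cambial-age classes centred every 10 years, half-open windows
`[c − 2.5, c + 2.5)` so integer ages partition cleanly (each tree-year
belongs to at most one class), class-mean BAI per calendar year, and an
OLS trend on calendar year (a weighting switch by trees-per-year
exists; unweighted is the default). Two exclusion rules apply: fewer
than 3 distinct calendar years, and — necessarily — fewer than 2
distinct trees, because within a single tree cambial age and calendar
year are perfectly confounded and no trend is identifiable.

**Spatial regressions.** Detrending each tree's BAI against its *own*
smoother would remove exactly the between-tree level differences a
landscape gradient creates, leaving the analysis powerless by
construction. The implementation therefore fits the age-dependent
smoother once per species to the pooled age-aligned BAI (the
species-average growth-at-age curve) and expresses each tree as its
mean *relative* deviation `mean(BAI/curve − 1)` — a unitless BAI index
that keeps one large old tree from dominating the fit. That index is
regressed on the distance covariate by OLS. One honest limitation: when
trees share a strong interannual signal their mean deviations are
cross-correlated, and plain OLS p-values become anti-conservative; the
null-calibration test therefore switches the common signal off, and
spatial p-values on signal-rich data (real or synthetic) should be read
with that in mind.

## The isotope chain

Bulk-wood δ¹³C is converted to leaf-equivalent values by subtracting
the post-photosynthetic enrichment `d = 2‰` (wood is enriched relative
to leaf; `d` is a parameter, `d = 0` treats samples as leaf tissue).
Discrimination, intercellular CO₂ and intrinsic water-use efficiency
follow the simple Farquhar formulation with `a = 4.4‰`, `b = 27‰` and
the 1.6 diffusivity ratio. The chain is algebraically invertible;
`delta13C_from_iwue()` is the exact inverse and the round trip holds to
1e-9 across δ ∈ [−32, −20]‰ and Cₐ ∈ [280, 420] ppm. Physically
impossible results (`C_i` outside [0, Cₐ]) are flagged, not dropped, so
the sample census stays auditable.

The packaged atmospheric history (`atmosphere_annual_synthetic.csv`,
1700–2022) is a monotone spline through ~15 hand-set anchor points at
the magnitudes of the published ice-core/flask compilations — adequate
for method development and simulation, and labelled synthetic in both
filename and documentation; users with a preferred compilation pass it
via `atmospheric_history(path)`.

**Age model and its confounding.** The ontogeny control fits, per
species, univariate OLS `iWUE ~ cambial_age` and takes residuals, as
the field does. In decadally subsampled tree data, cambial age and
calendar year are negatively entangled (old rings are old years), so
the univariate age slope absorbs part of any calendar trend and is
attenuated relative to the data-generating value; the same applies to
the univariate covariate regressions (temperature, CO₂ and the calendar
trend are collinear). The package keeps the univariate fits because
they are the method; the parameter-recovery checks in the tests and
acceptance script therefore fit the *joint* generative model
(age + post-1930 trend + temperature anomaly), which recovers all three
planted coefficients within their 95% CIs at the study's census sizes,
while an orthogonal factorial design (ages × years crossed) shows the
univariate two-stage estimates are unbiased exactly when age and year
are unconfounded.

## The synthetic study generator

`sim_config()` freezes the study conditions: 22/26/26 trees of
TAAS/TADI/PIEL with ages spanning 52–289, 46–219 and 46–162 years at
2022; per-species negative-exponential ontogeny
`(w0 − w∞) e^{−age/τ} + w∞` with parameters chosen to give mean radial
growth near 0.8/2.6/3.1 mm yr⁻¹ over typical lifespans; monthly climate
1895–2022 with wet-season (Apr–Oct) rainfall peaking ~260 mm/month
against a ~40 mm dry-season floor, temperature 18–27 °C, a
0.025 °C yr⁻¹ warming trend from 1979, and VPD peaking in the dry
spring; a water-depth gauge restricted to 1990–2021 with its September–
October maximum and April–May minimum, generated as smoothed
precipitation plus independent AR(1) noise mixed so precipitation
explains ~5% of the depth anomaly variance.

Growth is multiplicative and log-linear in the drivers:
`w = ontogeny(age) · exp(Σ β_k z_k(year) − σ_z²/2) · exp(ε − σ²/2)`,
with `z` the standardized June–September water-depth aggregate
(β = 0.35 by default), ε lognormal with σ = 0.3, and both exponentials
mean-corrected — without the signal's `−σ_z²/2` term, years inside the
instrumented span would be systematically wider than earlier years and
fake a calendar trend in the age-class analysis. Years before the
environment record carry no common signal, as with a real gauge.
Optional cohort (`cohort_beta`, log-growth per century of birth year)
and spatial (`spatial_effect`, log-growth per metre) effects exist for
recovery experiments and default to off.

The isotope generator prescribes
`iWUE = 85 − 0.1·age + 0.3·(year − 1930)₊ + 2·T_anom + N(0, 3)` and
inverts it *exactly* through the discrimination chain to wood δ¹³C, so
pipeline recovery tests are algebraically clean. Sampling follows the
decadal-then-bidecadal design (2020, 2010, …, 1880, then 1860…1800) on
16 fixed-age trees per species; because that grid applied to the
configured age structure yields more samples than the study censuses
(167/133/116), the grid is subsampled deterministically under the seed,
emulating incomplete recovery of datable wood. A grid smaller than the
census is an error, not a silent shortfall.

What the generator does *not* emulate — hurricane and fire disturbance
pulses, spatial autocorrelation among neighbouring trees, crossdating
error, and measurement error in δ¹³C beyond the trajectory noise — so
passing tests demonstrate correctness of the estimators under the
stated model, not robustness to those field realities.

## Numerical choices and problem sizes

Tolerances: biweight iteration 1e-8; BAI conservation 1e-9 relative;
isotope round trip 1e-9; curve floor 0.001 mm. Ties and degenerate
inputs: MAD = 0 → median; zero-variance predictors are skipped with
warnings; consecutive zero rings make the mean-sensitivity term 0/0 and
the pair is skipped with a warning; `r̄ ≤ 0` clips EPS.

The test suite and acceptance script size their simulations for
precision per unit cost as the package's own choices: 100 replicates of
a 20-tree chronology for the summer-window recovery rate, 1000–1500
independence-null replicates at n = 100 (rate SE ≈ 0.007–0.009) for the
bootstrap calibration, 1000 random series for BAI conservation, 25
replicates for the warming-trend unbiasedness check (a single 44-year
window has a slope SE near 20% of the trend, so a one-shot ±10% claim
would be testing luck, not code), and the full 416-sample census for
iWUE parameter recovery.

## Known limitations

* The age-dependent smoother is a reconstruction of the intent of
  age-dependent spline standardization (stiffness growing with age),
  not a line-for-line port of any particular program; chronology
  statistics on real data will differ in the second decimal from other
  implementations with unpublished internals.
* Percentile bootstrap significance is mildly liberal (see above); with
  28 windows per variable and no multiplicity correction, expect ~2
  spurious cells per variable at the realized rate.
* Univariate age and covariate regressions for iWUE are confounded by
  design of decadal sampling; effect sizes from them are descriptive,
  not causal estimates.
* Spatial OLS p-values assume independent trees; a shared interannual
  signal violates that and inflates significance.
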