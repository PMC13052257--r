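# swampdendro

Dendrochronology and tree-ring stable-isotope analysis for subtropical
wetland conifers — pond cypress (*Taxodium ascendens*), bald cypress
(*T. distichum*) and slash pine (*Pinus elliottii*) growing at the warm,
wet southern margins of their ranges, where standing-water depth, not
temperature or rainfall, is often the dominant control on radial growth.

The package is aimed at dendroecologists and tree ecophysiologists who
want a scripted, tested version of the classic workflow:

1. **Chronology construction** — read Tucson-format ring widths, remove
   the ontogenetic trend of each series with an age-dependent smoother
   (initial stiffness 20 yr, growing with cambial age), form the ring
   width index `RWI_t = w_t / g(age_t)`, prewhiten each index with an
   AR(p) model (AIC order selection), and average across trees with the
   Tukey biweight robust mean to a *residual chronology* with sample
   depth.
2. **Chronology quality** — mean sensitivity
   `MS = mean_t | 2 (x_t − x_{t−1}) / (x_t + x_{t−1}) |` (0–2, with
   0.2–0.6 the ideal band), series intercorrelation `r̄` (each series
   against the leave-one-out biweight master), and the expressed
   population signal `EPS = n r̄ / (n r̄ + 1 − r̄)`.
3. **Climate–growth correlation functions** — Pearson correlations of
   the chronology against 28 windows per variable (previous and current
   Jan…Dec, plus winter Jan–Mar and summer Jun–Sep seasons; sums for
   precipitation, means otherwise), with 95% confidence intervals from
   the stationary bootstrap (Politis–Romano geometric blocks, mean
   length `⌈n^{1/3}⌉`, paired resampling of years).
4. **Growth geometry** — basal area increment
   `BAI_t = π r_t² − π r_{t−1}²`, age-class-isolation trend regressions
   (5-yr cambial-age classes centred every 10 yr, class-mean BAI vs
   calendar year) and spatial regressions of age-detrended BAI on
   landscape distances (road, dome centre, pineland edge).
5. **Isotopes → iWUE** — the discrimination chain
   `δ¹³C → Δ¹³C = (δₐ − δ_leaf)/(1 + δ_leaf/1000)`,
   `C_i = C_a (Δ − a)/(b − a)` with `a = 4.4‰`, `b = 27‰`, and
   `iWUE = A/g_s = (C_a − C_i)/1.6` (µmol mol⁻¹), after subtracting the
   2‰ post-photosynthetic wood enrichment; then a per-species linear
   age model whose residuals are regressed on annual climate, water
   depth, CO₂ and growth.

A first-class **synthetic-data module** (`sim_config()`,
`simulate_study()`) generates ring widths, monthly climate, a short
water-gauge record whose variance is only ~5% explained by
precipitation, spatial covariates, and decadally subsampled δ¹³C series
with the same censuses and age structures as the field study the
workflow emulates — so every stage is testable offline, with ground
truth attached for parameter-recovery checks.

## Worked example

```r
library(swampdendro)

sim <- simulate_study(sim_config(seed = 7))   # three species, 74 trees
sp  <- vapply(sim$trees, `[[`, "", "species_code")

det   <- lapply(sim$trees[sp == "TADI"], detrend_series)
chron <- build_chronology(det)                 # residual flavor
chronology_quality(det)
```

```
chronology quality (n = 26 series)
  mean sensitivity: 0.461 (ideal)
  series intercorrelation rbar: 0.669
  expressed population signal: 0.981
```

The interannual variability sits in the ideal 0.2–0.6 sensitivity band,
and 26 trees sharing `r̄ = 0.67` give an EPS of 0.98 — comfortably above
the conventional 0.85 threshold for a usable chronology.

```r
cf <- correlation_function(chron, sim$environment$water_depth,
                           n_boot = 1000, seed = 7)
head(as.data.frame(cf)[order(-cf$r), ], 5)
```

```
      variable      window     r ci_low ci_high significant  n
28 water_depth curr.summer 0.965  0.950   0.978        TRUE 31
20 water_depth    curr.aug 0.786  0.660   0.877        TRUE 31
19 water_depth    curr.jul 0.774  0.577   0.890        TRUE 31
21 water_depth    curr.sep 0.722  0.594   0.861        TRUE 31
18 water_depth    curr.jun 0.442  0.107   0.687        TRUE 31
```

The generator plants a June–September water-depth sensitivity; the
correlation function finds exactly that: the summer-season window leads
(r = 0.97 over the 31 gauge years) with the individual summer months
behind it.

```r
rec <- age_detrend_iwue(iwue_pipeline(sim$isotopes))
subset(iwue_covariate_regressions(rec, sim$annual_covariates),
       species == "TADI")
```

```
   species covariate   slope r_squared  p_value   n
8     TADI mean_temp  8.2117    0.4223 2.41e-16 125
...
14    TADI        ca  0.2518    0.8334 1.07e-49 125
```

Age-corrected iWUE rises strongly with mean annual temperature and with
atmospheric CO₂ — the planted post-1930 trajectory seen through the
pipeline's own regressions.

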