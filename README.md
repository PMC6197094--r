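# chrysodev

Developmental models and minimum-postmortem-interval (PMI_min) estimation for
the oriental latrine fly *Chrysomya megacephala* (Diptera: Calliphoridae),
the dominant early colonizer of remains across much of China.

Forensic entomologists estimate PMI_min from the developmental state of the
oldest immature insects on a body plus the ambient temperature history. This
package provides, for the Yangtze River Delta (Suzhou) population reared at
seven constant temperatures (16–34 °C):

* the published reference tables as validated fixtures: per-stage mean ± SD
  durations, per-stage thermal constants, per-temperature cubic growth
  equations in both directions, and intra-puparial sub-stage (A–K) timing
  brackets;
* the **Ikemoto–Takai thermal summation model**: development completes when
  accumulated degree hours `ADH = ∫ max(T(t) − D0, 0) dt` reach the stage's
  thermal constant *K*; the linearized form regresses `y = D·T` on `x = D`
  so the OLS slope estimates the developmental threshold *D0* and the
  intercept estimates *K*;
* cubic larval growth curves `L(T)` and their inverse-prediction form
  `T(L)`, with peak-feeding detection, plus the classical **isomorphen** and
  **isomegalen** diagrams;
* **PMI_min inference**: degree-hour accumulation over arbitrary temperature
  records, backward inversion for the oviposition time with per-stage
  thresholds, sub-stage age bracketing with temperature interpolation, and
  composition of larval/pupal case evidence into an interval estimate with a
  full trace;
* a seeded **synthetic-cohort simulator** reproducing the rearing study's
  design (eight larvae sampled every 4 h, four replicates), so the whole
  pipeline is testable end to end against known truth.

## Worked example

Fit the thermal summation model for the total immature period and estimate
PMI_min for a 10 mm third-instar larva collected after 500 h of a constant
22 °C record:

```r
library(chrysodev)

fit_thermal_summation(cm_stage_durations(), "total")
#> Thermal summation fit (Ikemoto-Takai OLS, ols_means), stage 'total'
#>   D0 = 11.40 degC (SE 0.32)   K = 3826.8 ADH (SE 135.9)
#>   R2 = 0.9960 (adjusted 0.9953), n = 7

s  <- temperature_series(0:500, rep(22, 501))
ev <- case_evidence("larva_with_length", instar = 3, length_mm = 10,
                    collection_time_h = 500)
estimate_pmi(ev, s, cm_thermal_constants(),
             curves = cm_growth_curves("time_of_length"),
             durations = cm_stage_durations())
#> PMI_min estimate (anchor: oviposition)
#>   interval: 84.8 - 100.7 h (3.5 - 4.2 d)
#>   point estimate: 92.7 h
#>   notes:
#>    - predicted age 74.0 h falls outside instar 3's window [75.4, 184.0] h
```

Reading the output: the fitted line says this population needs ~3 827 degree
hours above a threshold of 11.4 °C to develop from egg to adult. The case
estimate ages the larva at ~74 h after hatching from the 22 °C inverse growth
cubic, adds the inverted egg stage (207.2 ADH at 22 − 10.91 °C ≈ 18.7 h), and
reports oviposition 85–101 h before collection; the note flags that a 10 mm
larva is marginal for instar 3 at this temperature (it sits at the
instar 2/3 boundary), which is worth a second look at the specimen rather
than silent acceptance.

Pupal evidence works the same way from the sub-stage table:

```r
substage_age_bracket(cm_substages(), "H", 28)   # pink-eye stage at 28 degC
#> min_h max_h
#>    72    80
```

## Scope notes

The packaged constants are population-specific and should not be transported
to other regions. The published total-period *K* (3 418.7 ADH) is internally
inconsistent with its own published slope and cannot be reproduced from the
mean durations (refitting gives ~3 827 ADH at the same slope); the fixture
stores the printed value with a provenance note and the package reports its
own fit. See the methods vignette
(`vignettes/pmi-estimation-methods.Rmd`) for model assumptions, numerical
choices, interval semantics and known limitations.
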