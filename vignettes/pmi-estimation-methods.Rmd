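---
title: "Thermal development models and PMI estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal development models and PMI estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrysodev)
```

## The problem

Blowflies colonize remains within hours of death, and their offspring develop
at a rate governed almost entirely by temperature. If the developmental state
of the oldest immature insects on a body can be measured — larval instar,
larval body length, or the morphological sub-stage of a pupa — and the ambient
temperature history is known, the time since colonization can be
reconstructed, which bounds the minimum postmortem interval (PMI~min~).
*Chrysomya megacephala* is the dominant early colonizer across much of China,
and this package packages the developmental reference data for its Yangtze
River Delta population (reared at constant 16, 19, 22, 25, 28, 31 and 34 °C)
together with the models needed to run the inference.

## The thermal summation model

Development is modelled as the accumulation of thermal time above a
developmental threshold temperature $D_0$: a stage completes when its
accumulated degree hours

$$\mathrm{ADH} = \int \max(T(t) - D_0,\; 0)\, dt$$

reach the stage's thermal summation constant $K$. At constant temperature
this is the hyperbola $D \cdot (T - D_0) = K$ relating duration $D$ to
temperature. The Ikemoto–Takai linearization fits this law by ordinary least
squares of $y = D \cdot T$ on $x = D$, so the slope estimates $D_0$ and the
intercept estimates $K$. `fit_thermal_summation()` implements exactly this
regression (via `stats::lm`); it reproduces the published per-stage constants
from the packaged mean durations:

```{r}
fit_thermal_summation(cm_stage_durations(), "egg")
```

Two numerical notes, both verifiable from the packaged data:

* **The published total-period $K$ is internally inconsistent.** Refitting the
  seven published mean total durations gives the published slope
  ($D_0 = 11.4$ °C) but an intercept near 3 827 degree hours, not the printed
  3 418.7; no regression line through these data can produce that
  slope–intercept pair. The fixture (`cm_thermal_constants()`) stores the
  printed value with a provenance note, and analyses that need a total-period
  model should refit it from the durations.
* **The published $R^2$ column matches the adjusted coefficient of
  determination.** The second-instar row is diagnostic: the plain $R^2$ of
  that fit is 0.978 (rounds to 0.98) while 0.97 is printed, which equals the
  adjusted value 0.974. `thermal_fit` objects therefore carry both `r2` and
  `adj_r2`.
* The published third-instar row (K = 1 077.6, $D_0$ = 11.57) is not exactly
  recoverable from the published mean durations either (a means-based refit
  gives K ≈ 1 031, $D_0$ ≈ 11.91); the other four stages and the total-period
  slope reproduce to well under a percent.

Standard errors are reported from the usual OLS formulas on whatever records
are supplied. Whether the original fits used replicate-level points or
temperature means is not stated in the source; fits on means reproduce the
published estimates, so means are the default and replicate rows are used
automatically when a table carries them. Printed SEs are therefore
indicative, not exactly reproducible.

### Degree-hour bookkeeping

`accumulate_degree_hours()` integrates the clipped excess temperature over a
timestamped record. Two interpolation modes are supported: `step` (hold the
last reading — the right semantics for an hourly logger, and the default) and
`linear` (trapezoidal, with the sub-threshold part of a crossing segment
clipped exactly rather than numerically). There is no upper temperature
cutoff: developmental failure is only reported near or above 37.5 °C for this
species, outside the modelled 16–34 °C range, so none of the packaged models
should be extrapolated there anyway.

Below the threshold accumulation is zero, never negative; the integral is
additive over adjacent intervals to machine precision (property-tested against
a 1-minute Riemann oracle).

## Growth curves and the two diagrams

Larval body length is the most informative ageing character up to **peak
feeding** — the time of maximum mean length, after which post-feeding larvae
shrink and length no longer determines age. The package fits cubic
polynomials in both directions (`fit_growth_curve()`): length as a function
of time after hatching, $L(T)$, over the whole larval record, and time as a
function of length, $T(L)$, on data truncated at peak feeding so the fitted
relation is invertible. The packaged equations
(`cm_growth_equations()`) store the published coefficients at full printed
precision, including the anomalous linear term of the 19 °C $L(T)$ equation
(−6.7×10⁻⁴ where neighbouring temperatures have +0.05 to +0.12), which is
kept as printed and flagged in the table's `note` column.

Because the published equations carry no validity windows, `growth_curves()`
reconstructs them: $L(T)$ curves run from hatching to the end of the larval
feeding span (sum of the three instar means at that temperature), and $T(L)$
curves from the paired curve's hatching length to its fitted peak length.

A genuine limitation, documented rather than hidden: **the inverse of a cubic
is not a cubic.** Even on noiseless data the fitted $T(L)$ cannot reproduce
$L(T)$'s inverse exactly, and the misfit grows with the span of the larval
period — at 16 °C (a ~300 h feeding span) the round-trip discrepancy reaches
tens of hours, and the independently fitted published pairs disagree by
similar amounts because each was fitted to noisy data. At 28–34 °C the
round trip is accurate to under 2 h away from the peak. The package's tests
assert the round-trip property exactly there: warm temperatures, lengths more
than one measurement-noise SD (0.3 mm) below peak, where inverse prediction
is well conditioned. Low-temperature, near-peak age estimates should be
treated as wide intervals, not points.

The two classical diagrams are direct constructions on these models:

* `build_isomorphen()` charts cumulative time from oviposition to each event
  (hatching, both ecdyses, pupariation, eclosion) against temperature, with
  SDs propagated in quadrature; for eclosion the directly observed total
  duration (with its own SD) is preferred over the sum of rounded stage
  means.
* `build_isomegalen()` draws constant-length contours in the
  (time, temperature) plane, solving each curve per temperature (direct
  evaluation for $T(L)$; root-finding restricted to the rising pre-peak
  branch for $L(T)$) and interpolating linearly in temperature between
  fitted curves. Contours are truncated with a note where a length is never
  reached (e.g. 16 mm exceeds the fitted peak at 34 °C).

## Pupal ageing

Intra-puparial morphology is classified into eleven sub-stages (A–K, from
the pre-pupal stage through the eye-colour series to the brown-eye stage)
with tabulated min/max hours post-pupariation at 16, 22, 28 and 34 °C.
`substage_age_bracket()` performs an exact lookup at those anchors and
interpolates both bounds linearly in temperature between them — the simplest
defensible rule given four anchors; it is recorded in every estimate's
policy list so results are labelled with the rule that produced them.
Temperatures outside 16–34 °C are refused rather than extrapolated. The
zero-width interval of sub-stage A at 34 °C (min = max = 0, a sampling
resolution artefact) is stored as printed and flagged by validation, not
rejected.

## Composing a case estimate

How reference models are combined into a case estimate is this package's own
procedure (the source data end at the individual models), and
`estimate_pmi()` labels its output accordingly. The interval is anchored at
oviposition by default — the forensic convention, since oviposition is the
earliest insect activity — with `anchor = "hatching"` available.

* **Larva with length.** The larva is aged by evaluating $T(L)$ at the two
  fitted temperatures bracketing the effective temperature and interpolating
  linearly; the effective temperature is the time-weighted series mean over
  the candidate larval window, iterated once. The egg stage is then inverted
  backward through the record. The interval inverts the length at
  $L \pm 2\sigma_L$ (default $\sigma_L$ = 0.3 mm, the simulator's
  measurement-noise default) and widens by ±2 SD of the egg duration when a
  duration table is supplied. With an instar supplied, the age is
  cross-checked against the instar's time window: mild conflicts warn,
  conflicts beyond a full window width are rejected as inconsistent
  evidence.
* **Larva staged to instar only.** The interval spans the instar's onset to
  offset, each found by backward inversion of the stages before it.
* **Pupa with sub-stage.** The bracket is looked up at an effective
  temperature defined as the ADH-weighted series mean over the candidate
  pupal window (weighting by development rate, iterated once), then the
  pre-pupal span is inverted backward from the bracket's endpoints.
* **Empty puparium.** Eclosion has occurred: lower bound only.

The backward inversion (`invert_oviposition_time()`) consumes each stage's
$K$ against its own $D_0$ in reverse order, locating each stage boundary with
`stats::uniroot` on the exact closed-form accumulator (tolerance 1e-10 on
time, so constant-temperature cases agree with
$\sum_i K_i / (T - D_{0,i})$ to better than 1e-6 h). Per-stage thresholds are
used rather than the single total-period pair because the fitted thresholds
genuinely differ across stages (10.3–13.4 °C). For the pre-pupal span behind
pupal evidence a `prepupal = "duration_table"` policy is available that reads
the rearing-duration table (interpolated in temperature) instead of the
thermal fits; it reproduces the published durations exactly at the rearing
temperatures but assumes a near-constant record. The two policies agree
within ~6 % at the rearing temperatures — the same accuracy envelope as the
thermal model's duration predictions, which are within 6 % of the observed
totals at all seven temperatures.

Degenerate and edge inputs are handled explicitly: a record that does not
reach back to oviposition raises an insufficient-record error reporting the
degree-hour shortfall; temperatures at or below a threshold raise a
no-development error; lengths outside a curve's window are a domain error;
negative predicted ages are clamped to zero with a warning.

## The synthetic-cohort simulator

The simulator exists so every stage of the pipeline can be tested end to end
with known truth; its defaults are the rearing study's own conditions: seven
constant temperatures, four replicates, eight larvae sampled every 4 h,
stage durations with the published means and SDs, lengths from the published
cubics plus Gaussian measurement noise of SD 0.3 mm (chosen so simulated
growth-curve fits land in the ≥0.985 R² range of the published ones).

Generative assumptions, and what they deliberately do not model:

* Stage durations are normal with a hard floor at 0.2× the mean (no
  distributional form is reported in the source; the floor prevents
  nonphysical durations). Successive stages are independent by default; a
  `stage_correlation` knob exists (default 0) because no correlation
  structure is reported.
* The published SDs are SDs of four replicate means, which leaves the
  individual-level variance unidentified. `sd_interpretation =
  "replicate_means"` (default) draws a replicate-level shift with the
  tabulated SD and reuses the same SD within replicates;
  `"individuals"` applies it to individuals only. Both are exposed because
  the source does not disambiguate.
* No maggot-mass thermogenesis, no mortality, no oviposition delay, no
  diapause: passing tests show the *inference machinery* is correct under
  the stated generative model, not that real casework carries these error
  bars.

Determinism is contractual: a seed is mandatory, every cohort draws from a
substream derived from (seed, temperature, replicate), and the caller's RNG
state is untouched.

Problem sizes used in the shipped tests were chosen to exercise the
statistics at meaningful scale while keeping the suite quick: cohorts of
40–200 individuals, four-replicate designs across the seven temperatures,
100 simulated length cases for interval coverage, and 20 seeded replicates of
the full design for parameter recovery (recovered $D_0$ within 0.5 °C and
$K$ within 5 % in median).

## Known limitations

* All models are population-specific; other *C. megacephala* populations
  develop measurably faster or slower, so the packaged constants should not
  be transported across regions.
* The reference data are constant-temperature rearing; applying the models
  to fluctuating records assumes rate additivity (the degree-hour law),
  which is untested for this population outside 16–34 °C.
* Inverse age-from-length prediction degrades near peak feeding and at low
  temperatures (see above); the interval semantics reflect measurement noise
  and egg-duration spread but not model misspecification.
* Intervals are range-based, not probabilistic: no confidence level is
  attached.
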