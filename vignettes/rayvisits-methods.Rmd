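---
title: "Methods: residence events, covariate annotation and mixed models for ray telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residence events, covariate annotation and mixed models for ray telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rayvisits)
```

`rayvisits` analyses passive acoustic telemetry of two durophagous ray taxa
around clam aquaculture leases. This vignette is the package's own account
of the procedures it implements: the residence-event model, each
annotation, the two model families, and the synthetic generator used to
validate them — including the numerical and design choices that were
genuinely open, and what the validation does and does not establish.

## From detections to visits

The atomic record is a *detection*: one transmitter ping logged by one
receiver at one instant (UTC, second resolution). Receivers have a nominal
200 m detection radius; tags transmit at uniform random intervals
(V13: 60–180 s; V16: 30–90 s).

**Duplicate and false-positive filtering.** Concatenated receiver
downloads produce exact duplicates, removed by
`dedup_detections()` (idempotent). Tag-collision artifacts tend to appear
as isolated pings, so `filter_false_detections()` applies a reproducible
isolation rule: a detection is discarded when fewer than `min_hits = 2`
detections of the same tag (itself included, anywhere in the array) fall
within ±`window_min = 60` minutes. Both parameters are exposed because no
universal criterion exists; field studies often filter such records
manually, which is not reproducible. The filter is validated against an
all-pairs brute-force oracle.

**The time-out.** A visit should tolerate gaps no longer than the time an
animal needs to traverse the detection area. With a 400 m detection
diameter and an eagle-ray rate of movement of 1.4 km h⁻¹,

```{r}
compute_timeout(detection_diameter_m = 400, rom_km_h = 1.4)
```

minutes. The division is carried at full precision internally; the
one-decimal value (17.1) is the reporting and default-threshold
convention.

**Visit extraction.** Per transmitter, detections are scanned
chronologically across all receivers. A run continues while the receiver
is unchanged and the gap to the previous detection is *at most* the
time-out; it ends on a strictly larger gap or on a detection at another
receiver; runs with ≥ 2 detections become visits with duration = last −
first detection. Two boundary conventions were open and are fixed as:

- *Inclusive gap rule*: a gap of exactly the time-out continues the visit,
  because termination is defined by a gap *greater than* the time-out.
- *Same-second detections on two receivers* are processed in receiver-ID
  lexical order, which deterministically splits both runs — consistent
  with the new-receiver rule and stable across platforms.

Visits with duration strictly greater than 17.1 min are classed *long*
(so a visit of exactly 17.1 min is short). Extraction is verified against
an independent brute-force segmentation oracle on random logs up to 1,000
detections with random time-outs, plus a monotonicity property: enlarging
the time-out can only merge visits, never split them.

## Annotation

**Diel class.** Day is the half-open local-clock interval
[07:00, 19:00) in `America/New_York`; everything else is night. The fixed
window is the mean sunrise/sunset over the 2017–2019 study period at
Sebastian, FL rounded to the nearest hour, and `derive_diel_window()`
regenerates it for any site from a standard solar-position algorithm
(NOAA equations, zenith 90.833°). Timestamps are stored UTC and converted
at the point of classification; the timezone is configurable because
detection hardware logs UTC while diel behaviour follows the local clock.

**Moon fraction.** A low-precision lunar phase-angle algorithm (polynomial
mean elements with the principal periodic corrections) returns the
illuminated fraction in [0, 1]. It is tested against published almanac
full- and new-moon times for 2017–2019 (≥ 0.99 at full, ≤ 0.01 at new,
≥ 0.95 within ±1 day of full).

**Tide state.** Receivers experience the tide later than the reference
station. The tidal rate of movement is TRM = d/ΔT; with the reference
distance d = 3,698 m and lag ΔT = 2 h 20 min, TRM = 0.4402 m s⁻¹ (some
reports round this to 0.439 from unstated precision; the package keeps
full precision — `tide_offset()` is the exact inverse of `compute_trm()`).
Each receiver's lag is its great-circle distance to the reference divided
by TRM. Discretization of the four tide states is not standardized
anywhere, so the package adopts a symmetric slack-band rule: within 1/8 of
a full cycle of a predicted high (low) extremum the state is High (Low);
otherwise Incoming on the rising limb, Outgoing on the falling. Over a
uniform cycle each state occupies a quarter of the time, which the tests
assert on a synthetic semidiurnal series. The band fraction is tunable.

**Season and study year.** Seasons change at the tabulated astronomical
equinoxes and solstices (2016–2020); study years run June–May (Y1 =
2017-06-01…2018-05-31, Y2 = 2018-06-01…2019-05-31), both configurable.

**Environment.** Water-quality series are joined to visit start times by
nearest timestamp within a 30-minute tolerance (the series are hourly;
beyond tolerance the covariates are `NA`, the count is messaged, and such
visits drop out of models). The tolerance is a free parameter with no
field standard; 30 min keeps the worst-case mismatch at half the sampling
interval.

## Summary tables

Summaries are keyed by species × receiver with explicit margin rows:
detection counts with per-species shares, day/night means ± SE over
per-tag-per-date cells (the averaging unit is switchable to per-tag
totals), visit duration range/mean ± SE/count/total time, visit-time
shares over receiver groups, and strict-threshold long-visit counts.
Percentages are rounded half-away-from-zero to one decimal, matching the
convention apparent in published tables; SE for a single-observation cell
is reported as 0 by convention. Margins are asserted to equal cell sums
exactly, and the summary operations reproduce, from transcribed published
per-receiver cells, every derived share used in the acceptance checks
(e.g. 64.5% of eagle-ray detections at the inlet receiver SINJ, an 11.3%
pooled cownose clam-lease share, an 85.3% eagle-ray inlet visit-time
share).

## Models

**Detection counts.** The modelling unit is the per-tag × local date ×
receiver × diel cell (`detection_cells()`), zero-filled over each tag's
detected date span so absences inform the model — the aggregation unit is
exposed because no single convention exists. `fit_detection_glmm()` fits
a Poisson GLMM (log link, Laplace approximation, `lme4::glmer`) with, by
default, the full time-of-day × receiver × sex interaction and a random
intercept per transmitter. Singular (boundary) variance estimates are
reported as converged-with-zero-variance, while genuine optimizer
failures are flagged and never silently worked around.
`pairwise_contrasts()` computes estimated marginal means on the link
scale and all pairwise differences with Tukey studentized-range
adjustment.

**Visit durations.** `fit_visit_gamm()` fits a Gamma GAMM (`mgcv::gam`,
REML smoothing selection) with smooths of decimal hour (cyclic basis —
midnight is one instant), moon fraction, temperature, salinity and
dissolved oxygen, parametric tide-state and location terms, and a
penalized random intercept per animal. Basis dimension defaults to k = 9
per smooth (reference df 8 plus the identifiability constraint). The
inverse link is attempted first because it is the conventional canonical
choice for this analysis; it lacks guaranteed positivity, so failure or
non-convergence triggers a documented log-link refit flagged
`link_fallback` in the result.

**Collinearity.** `collinearity_screen()` reports pairwise Pearson
correlations and VIFs (each covariate on all others) and drops offenders
iteratively — always the later-listed of a collinear set, so of a
temperature/oxygen-saturation pair the first-listed temperature survives —
with a default threshold of 3. Constant columns are flagged rather than
silently handled.

**Model selection.** `aicc_model_selection()` enumerates every subset of
the smooth and parametric terms (random intercept always retained),
ranks by AICc = AIC + 2k(k+1)/(n−k−1) with the n ≤ k+1 guard returning
infinity, reports ΔAICc and Akaike weights, breaks ties within 0.01
toward fewer terms, and records non-converging subsets without ranking
them.

## The synthetic generator

`simulate_telemetry()` produces detection logs with known ground truth.
Movement is site-level, not spatially continuous: animals alternate
exponential out-of-array absences (with a summer multiplier emulating
seasonal emigration for the cownose parameterizations) and Gamma
occupancy bouts whose log mean responds to local hour (cosine), moon
fraction, clam-lease location and tide state; site choice uses
diel-dependent weights (eagle rays inlet-heavy by day, lagoon-heavy by
night; cownose rays lagoon-heavy throughout). Within bouts, ping trains
are uniform-interval renewals thinned by the detection probability
(default 0.7); spurious detections with foreign tag IDs arrive as a
Poisson process to exercise the false-positive filter. Environmental
series include an oxygen-saturation column constructed collinear with
temperature specifically so the screening step has something real to
catch. All randomness derives from one integer seed; identical
config + seed gives byte-identical CSVs.

The defaults mirror the study conditions — six named receivers, a
2017-06-01…2019-05-31 window, 20 V13-tagged eagle rays, 14 + 4 V16-tagged
cownose rays, 200 m radii — with site coordinates that are synthetic
stand-ins placed so the inlet/river-mouth separation matches the 3,698 m
reference tide-lag distance. What the generator does *not* emulate:
acoustic propagation physics, range-test detection curves, spatially
continuous movement, receiver outages, or clock drift. Passing tests
therefore establish algorithmic correctness on idealized data, not
robustness to every field artifact.

## Validation design and problem sizes

The test suite runs at sizes chosen to keep the full suite to a few
minutes while leaving each check statistically meaningful:

- Oracle-equivalence and filtering checks use random logs of 100–1,000
  detections.
- End-to-end recovery uses a 45-day, 5-tag V16 deployment at detection
  probability 0.95 and requires ≥ 90% of ground-truth residence events
  recovered with interval Jaccard ≥ 0.8. The truth table first merges
  consecutive same-site bouts separated by less than the time-out, since
  no detector can distinguish those from continued residence. V16 tags
  (mean ping gap 60 s) are used because edge-ping loss — about one mean
  gap of unobserved time per visit — bounds the attainable Jaccard for
  short bouts: with 120 s V13 gaps, bouts under ~10 min cannot reach 0.8
  regardless of extractor quality.
- GLMM checks: 95% CI coverage of a known day/night rate ratio of 2 over
  200 tag-day cells × 100 replicates; null-uniform diel p-values over
  200 replicates (Kolmogorov–Smirnov); a sex term fit to sex-free data
  staying |z| < 2 in ≥ 90% of 50 replicates.
- GAMM checks: hour-smooth peak within ±1.5 h and response-scale shape
  correlation ≥ 0.9 at n = 2,000; a +30% clam-lease duration effect
  detected in ≥ 80% of replicates at n = 2,000; null calibration at
  n = 500 per replicate over 200 replicates — the penalized-smooth
  p-value approximation is measurably anti-conservative at n = 300, so
  the calibration is run where its premise holds; subset selection
  recovering exactly the true {hour, moon} term set against a spurious
  temperature candidate in ≥ 80% of 50 replicates. With AICc selection
  the probability of retaining any one spurious covariate is ~15%, which
  is why the exact-set criterion is paired with a small candidate set.

## Known limitations

- The tide lag model assumes a constant propagation speed along
  great-circle distances; bathymetry-driven variation is out of scope.
- The false-positive rule is a proxy for vendor collision diagnostics; it
  will discard genuine single fly-by pings and keep coincident collision
  pairs.
- Environmental covariates come from one station; spatial gradients
  across receivers are not represented.
- The Gamma GAMM's inverse link can place linear-predictor values near
  zero for long-visit regimes; the log-link fallback changes the
  coefficient scale (results flag which link was used).
- Published coefficient tables from field data are not reproducible
  without the raw detections; model validation is therefore by parameter
  recovery on synthetic data, not by coefficient comparison.
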