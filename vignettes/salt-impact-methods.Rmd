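---
title: "Modelling deaths averted by salt limits in bread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deaths averted by salt limits in bread}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltimpact)
```

## The problem

Bread is one of the largest sources of dietary sodium in Portugal: survey
data put mean intake at 100.3 g of bread and 7.4 g of salt per person per
day, with 18.2% of that salt coming from bread. Portuguese law caps bread
salt at 1.4 g per 100 g, but traditional and imported bread — nearly half
the market — is exempt, and a proposed tightening to 1.0 g/100 g for all
bread was rejected on free-trade grounds. `saltimpact` estimates the
mortality consequences of such policy options with a comparative risk
assessment (CRA): how many of the baseline year's cardiovascular deaths
would not have occurred had population salt intake been lower.

The pipeline has three stages, each usable on its own:

1. **Market model** — decompose annual bread tonnage into regulated and
   exempt segments and calibrate per-segment salt densities;
2. **Scenario engine** — convert a legal threshold into a per-capita
   intake reduction;
3. **Mortality model** — convert the intake shift into cause-specific
   deaths averted across age/sex strata, with Monte Carlo confidence
   intervals and a sensitivity battery.

## Market decomposition and the salt-density closure

`decompose_market()` is bookkeeping: pre-packaged sales minus imports
gives national pre-packaged bread; total minus pre-packaged gives loose
bakery bread; the traditional fraction applies to national production
(total minus imports), and exempt = traditional + imported. Applying the
published 2016 constants (`portugal_market_fixture()`) reproduces the
published segmentation exactly: 18,276 t national pre-packaged (4.86%),
89.36% loose, 181,268 t exempt (48.18%, of which 88% traditional).

The published annual total (376,218 t) is carried as a separate parity
input because per-capita intake times the rounded 10.3 M population gives
377,336 t; the published figure implies an unrounded population near
10.27 M. Computation accepts either.

No measurements of segment-level salt content exist, so
`calibrate_segment_salt()` imposes a closure: the regulated segment is
split into a compliant part at the voluntary 1.0 g/100 g level (76% of
bakeries in the main model) and a non-compliant part at the 1.4 g legal
maximum, and the exempt-segment density is the free parameter solved so
that the tonnage-weighted mean equals the survey-implied market mean

$$\bar d = \frac{\text{share} \times \text{salt intake}}{\text{bread
intake}} \times 100 = \frac{0.182 \times 7.4}{100.3} \times 100
= 1.343\ \text{g/100 g}.$$

Under the main-model assumptions the closure puts exempt bread at
1.608 g/100 g. A closure solution below zero or above 10 g/100 g aborts
as implausible. The closure guarantees, by construction, that total bread
salt equals 18.2% of intake; the tonnage-weighted mean matches the target
to 1e-9 (tested).

`scenario_reduction()` caps every in-scope segment at the scenario
threshold (`all_bread` removes the exemptions; `non_exempt_only` is the
current legal scope), leaves segments already below it untouched, and
aggregates the weighted density excess. The per-capita reduction is
computed on the consumption side (excess × per-capita bread intake / 100)
and tonnes/day follow by the exact identity `t/day = g/capita/day ×
population / 1e6`, so the two reported figures can never disagree. For
the 1.0 g cap on all bread this yields 0.344 g/capita/day (3.54 t/day),
i.e. intake falling 7.40 → 7.06 g/day.

A caveat worth stating plainly: no single exempt-segment density
reproduces every published reduction figure for the 1.4 g scenario family,
so the attribution is exposed as configuration (`compliant_level`,
`noncompliant_level`, compliance) rather than hard-coded; the calibrated
default reproduces the 1.0 g-cap figures within rounding.

## From intake shift to deaths averted

The mortality model is a potential-impact-fraction CRA. For each cause
and stratum, relative risk is log-linear in salt intake,
$RR(x) = \exp\{\beta (x - x_0)\}$, either with a directly specified
$\beta$ per g/day or mediated through systolic blood pressure
($\beta = \text{mmHg per g} \times \log RR\ \text{per mmHg}$, two
log-linear stages composed). The potential impact fraction for a shift of
the exposure distribution from $F_b$ to $F_c$ is

$$\mathrm{PIF} = 1 - \frac{E_{F_c}[RR]}{E_{F_b}[RR]},$$

and deaths averted in a stratum are `deaths × PIF`, summed over strata
and causes (`deaths_averted()`). Totals, sex and cause margins, and an
under-75 margin (age bands whose upper bound is ≤ 75) are reported.

The exposure family defaults to a point mass at the mean — the
deterministic-shift model, under which the PIF collapses to the closed
form $1 - \exp(\beta \Delta)$ that the tests use as oracle. A normal
family truncated at 0 g/day is provided for distributional fidelity;
expectations use fixed-order Gauss–Hermite quadrature (order 64, a
configuration knob), with truncation handled by discarding and
renormalising nodes below zero. For the untruncated case the quadrature
matches the log-normal-mean closed form
$\exp(\beta\mu' + \beta^2\sigma^2/2)$ to better than 1e-6 relative for
$|\beta|\sigma \le 1$; in the dietary regime (mean ≈ 7.4 g, sd ≈ 1 g) the
truncation correction is below 1e-8 (both tested).

## Uncertainty propagation

The central estimate is deterministic — computed at the point
dose-response parameters and independent of seeds and draw counts.
Confidence intervals come from Monte Carlo: each effective log-RR slope is
sampled independently as $N(\beta, se)$ on the log-risk scale
(`sample_dose_response()`), total deaths averted is re-evaluated per draw,
and the interval is the empirical 2.5th/97.5th percentile with linear
interpolation between order statistics (quantile type 7 — fixed and
documented because endpoints depend on the definition). Defaults are
10,000 draws and a mandatory seed; inside a battery each scenario uses
`seed + row index`, making whole tables bit-for-bit reproducible.
Uncertainty is propagated for dose-response slopes only; market and
demographic inputs are treated as fixed and explored through the discrete
scenario battery instead, mirroring the deterministic-result-plus-interval
design of the source analysis.

Properties asserted by the suite: zero standard errors collapse the
interval onto the central value; fixed seeds reproduce batteries
identically; the nominal 95% interval covers a known synthetic truth in
≈95% of 200 replicated simulations (binomial 3σ band, ≥180/200); known
slopes are recovered from draw means within 3 Monte Carlo standard errors
and from the pipeline's PIF by closed-form inversion.

## The scenario battery

`default_battery()` holds the twelve report rows: the two counterfactuals
(1.4 g and 1.0 g caps on all bread) and ten sensitivity variants.
Operationalisations where the source tables leave room:

* **Compliance (SA1)** re-runs the calibration at 100%/50% compliance
  before applying the cap — compliance changes where the salt sits, hence
  what the cap removes.
* **Urinary-sodium baseline (SA2, 10.7 g/day)** keeps bread at 18.2% of
  the *new* baseline and recalibrates the market from it, which is why its
  reductions exceed the main model's.
* **Bread share ±1 point (SA3)** is applied as `reduction ± 0.01 ×
  baseline` (±0.074 g at the 7.4 g baseline): the published rows move by
  exactly that amount, e.g. 0.35 → 0.42/0.27. Rescaling the share inside
  the market model (18.2 → 19.2/17.2%) is available instead via the
  `bread_share_of_salt` field of `scenario_spec()`.
* **Lower baseline (SA4, −1%)** scales the baseline *before* the market
  calibration so the implied density and closure shift with it; this
  reproduces the published SA4 reduction column, where scaling only the
  final number would not.

A negative adjusted reduction is clipped to zero with a warning, and the
counterfactual intake is never negative. Duplicate labels are rejected;
any scenario failure aborts with the failing label.

## The synthetic-data generator

The stratified national mortality table behind the published headline
counts is not redistributable, so `generate_strata()` emulates its
schema and qualitative shape: 18 five-year age bands (85+ open) by sex;
population plateauing through mid-life and declining logistically at old
age with the female decline centred later (72 vs 78), so the oldest bands
carry a female excess; Gompertz-like cardiovascular death rates
(`exp(0.095 × (age − 85))`) with a 1.5× male rate excess, normalised to
per-cause national totals and perturbed with seeded negative-binomial
noise (dispersion 100). The default cause totals (~28,400 deaths across
the seven salt-related causes) are synthetic magnitudes plausible for a
southern-European country of ten million — roughly 29% of ~110,000 annual
deaths being cardiovascular — chosen once and documented here, not
calibrated to reproduce any published estimate.

What the generator does *not* emulate: real cohort effects, cause-coding
practice, migration, or the joint distribution of salt intake with age
and sex. Passing tests therefore demonstrate the *mechanics* of the
pipeline (conservation, closed-form agreement, coverage, determinism) on
realistic shapes — not that the package reproduces national headline
mortality figures, which additionally require the exact demographic table
and dose-response file of the original analysis.

`generate_dose_response()` emits one direct-pathway entry per cause with
known true slope and `se = se_scale × |β|`, enabling exact closed-form
end-to-end checks. The packaged default parameter file
(`default_dose_response()`) is different in kind: an age-graded
salt→SBP→cause parameterisation assembled from published meta-analysis
magnitudes, shipped as a reasonable default for demonstration runs; no
test depends on its numeric values.

## Numerical choices

* Year length 365.25 days; tonne = 1e6 g; all masses internally in
  g/person/day, converted at the boundary.
* Full floating precision everywhere; rounding to report precision (two
  decimals for intake, integers for deaths) only in `format_battery()` /
  `write_battery_results()`.
* Gauss–Hermite order 64; percentile type 7; dose-response matching must
  be unique per (cause, age, sex) — zero or multiple matches are errors,
  not silent choices.
* Problem sizes used by the test suite and acceptance script: 252-row
  strata tables (18 × 2 × 7), batteries of 12 scenarios at 400–10,000
  draws, and 200-replication coverage runs — sizes at which every
  property is checked in seconds while Monte Carlo error stays well
  inside the asserted bands.

## Limitations

Single-baseline-year counterfactual only: no time lags, no projection, no
morbidity or non-fatal incidence (the model therefore understates total
health impact). No consumer substitution toward other salty foods. Market
uncertainty (tonnages, shares) is scenario-based, not sampled. The
dose-response defaults are literature-scale, not a calibrated national
parameter file.
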