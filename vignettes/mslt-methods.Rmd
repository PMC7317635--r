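---
title: "Methods: the proportional multistate life table and its synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the proportional multistate life table and its synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamslt)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical conventions, and the design choices
that were genuinely open.

## The model

The engine is a *proportional multistate life table* (MSLT): a main
all-cause life table per population stratum, with parallel three-state
disease life tables in which proportions of each cohort simultaneously
reside. The population is closed — every cohort alive in the base year
(ages 0–109, by sex and ethnicity) is advanced annually until extinction at
age 110; there are no births or migration.

Each disease table has states *healthy/cured*, *prevalent*, and *dead from
the disease*, driven by annual incidence $i(a)$, case fatality $f(a)$, and
remission $r(a)$ (non-zero for cancers only). Within a cycle, transitions
resolve in a fixed order: case fatality first, then remission, then
incidence (so mass remitted within a cycle is immediately at risk of
re-incidence). All rates are treated as annual transition probabilities;
the synthetic generator guarantees they lie in $[0,1)$, and the engine
rejects $i \times (1-\mathrm{PIF}) > 1$ as a rate/probability confusion.

An intervention acts only through disease incidence. The population's
weekly moderate-to-vigorous physical activity (MVPA), in MET-minutes per
week, is held as a categorical distribution on eight fixed bins
(0, 1–149, 150–299, 300–599, 600–1199, 1200–2399, 2400–4799, ≥4800).
Shifting a fraction of each bin's mass up by $\delta$ MET-min/week yields a
counterfactual distribution $p'$, and with relative risks evaluated at bin
midpoints the *population impact fraction* is the exact sum

$$\mathrm{PIF} = \frac{\sum_i p_i RR_i - \sum_i p'_i RR_i}{\sum_i p_i RR_i}.$$

Disease does not respond to exposure instantly: the effective PIF applied
in a given year is the unweighted mean of annual PIFs over an inclusive
integer lag window — offsets 0–5 years (6 terms) for coronary heart
disease, stroke and type 2 diabetes, and 10–30 years (21 terms) for the
cancers — with years before the intervention contributing zero. Whether the
original family of models weights the window uniformly is not documented in
the accessible sources; equal weights are implemented and flagged here as a
declared choice (a constant PIF series is invariant to the weighting, so
the convention only matters for transient effects such as the one-off
campaign).

The feedback from disease to survival is *additive in rates*: intervention
all-cause mortality is the baseline rate minus the summed change in
disease-specific mortality rates between scenarios, and morbidity (the
prevalent years-lived-with-disability rate, pYLD) is adjusted the same way
through disease disability weights on prevalence. Adjusted rates are
clipped to valid ranges and clip events are counted; under the default
synthetic world no clipping occurs (this is tested). Quality-adjusted life
years accrue as $l(a)\,(1-\mathrm{pYLD}(a))$, where everyone alive at the
start of a cycle accrues that full year — no half-cycle correction is
applied (the correction largely cancels in the BAU-vs-intervention
difference that all outputs are built from; the individual-level oracle in
the test suite uses the same convention, so the equivalence tests are
exact, not approximate).

## The intervention pathway

The modelled intervention is a one-off national mass-media campaign
promoting physical-activity smartphone apps. Of the eligible population
(ages 15–79), a cascade reaches the behaviour change:

| parameter | central | 95% interval | distribution |
|---|---|---|---|
| awareness of the campaign | 0.779 | 0.70–0.83 | beta |
| downloaded an app | 0.31 | 0.21–0.41 | beta |
| used the app (≥7 days) | 0.16 | 0.10–0.36 | beta |
| adhered (weighted annual average) | 0.15 | 0.10–0.21 | beta |
| effect size (MET-min/week) | 285 | SD 43 | normal, truncated at 0 |
| campaign cost (NZ$) | 2,883,000 | SD 20% | gamma |

The effect size derives from a reported 1404 steps/day increase at 34.5
steps per MVPA-MET-minute (`steps_to_met_minutes(1404)` ≈ 285), equivalent
to about 1.6 hours of brisk walking (MET 3.0) per week. The campaign has no
effect beyond its first year (`effect_duration = 1`); the 5-year
maintenance scenario sets 5. The full cost falls in year 0 and is *not*
varied across eligibility scenarios (the age-restricted scenario keeps the
national campaign cost).

**Adherence ambiguity.** The sources are ambiguous about whether the 15%
adherence scales the *population fraction* affected (with the full 285
MET-min effect) or the *effect size* (for the larger aware × download × use
fraction). Both readings are implemented (`adherence_mode = "fraction"`,
the default, or `"effect"`). They are *not* numerically equivalent here:
the near-linearity of the PIF in (fraction × effect) holds only for shifts
larger than the bin granularity, and 285 × 0.15 ≈ 43 MET-min is below most
bin widths, so midpoint evaluation absorbs part of an effect-scaled shift.
The fraction mode is the default both because the pathway table frames 15%
as a proportion of users and because it avoids this discretisation loss.

## The synthetic world

No real survey, burden-of-disease or costing inputs are distributed with
the package; the generator produces tables with the structure the model
assumes, under a single fixed scenario (`synthetic_scenario()`):

- **Population**: 4.4 million people (the 2011 national scale), two sexes ×
  two ethnic groups (an indigenous group, 15% of the population and younger
  on average, and the remainder), single year of age 0–109.
- **Mortality**: Gompertz–Makeham $q(a) = A + B e^{ga}$ with $A = 2\times
  10^{-4}$, $B = 3\times10^{-5}$, $g = 0.095$, female multiplier 0.8 and
  indigenous multiplier 1.6 — monotone in age by construction, with the
  indigenous-vs-other gap that makes the equity adjustment non-trivial.
- **Morbidity**: $\mathrm{pYLD}(a) = 0.03 + 0.12\,(a/100)^2$, indigenous
  multiplier 1.3.
- **Diseases**: incidence and case fatality rise exponentially with age
  from reference values at age 60, with sex/ethnicity multipliers; breast
  cancer exists only in female strata; remission 8–10%/year for the
  cancers, zero otherwise. After generation, a birth-cohort sweep audits
  that summed implied disease mortality stays below 90% of all-cause
  mortality in every stratum–age cell; violations trigger 20% damping and
  retry (at most five rounds, then an error).
- **Exposure**: zero-inflated (10%) log-normal MET-minute distributions per
  stratum (sdlog 1.15, male/indigenous location offsets, seeded jitter),
  binned onto the eight-bin grid and calibrated by a single global location
  shift so the population-weighted share of adults (15–79) below 450
  MET-min/week — 150 guideline minutes at MET 3.0 — is exactly 42%, the
  reported national prevalence of insufficient activity. The share below a
  threshold interpolates uniformly within a straddling bin.
- **Relative risks**: log-linear in MET-min/week, anchored at RR = 1 for
  the inactive bin, floored at 0.5, with per-disease RR at 600 MET-min/week
  between 0.88 (type 2 diabetes) and 0.95 (breast cancer). The magnitudes
  are deliberately placeholder — the literature-derived values live in an
  inaccessible technical report — but the qualitative shape (protective,
  monotone, bounded) is what every downstream property relies on. Setting
  the scenario's `rr_params$scale` to 0 gives the exact null.
- **Costs**: per-disease phase costs (first year NZ$4,000–32,000,
  subsequent years NZ$1,600–4,800, last six months NZ$15,000–45,000) with a
  common seeded stratum multiplier, so the generator constraint
  last-6-months ≥ subsequent-year holds by construction; per-capita
  unrelated annual cost $1200\,e^{0.025a}$ (≈NZ$3,300 at 40, ≈NZ$8,900 at
  80).

Identical scenarios produce byte-identical tables (the few stochastic
elements draw from the scenario seed under a restored RNG state).

**What a green test does not establish.** The generator emulates structure,
not levels: its disease rates, risk magnitudes and costs are plausible but
not estimated from any data, so absolute outputs (QALYs, ICERs) characterise
the synthetic world only. The properties the tests pin down are the ones
that transfer: unit conversions, oracle equivalence of the engine, exact
null propagation, discount and scenario orderings, the direction of the
equity adjustment, and the Monte Carlo contracts.

## Numerical choices

- **Determinism**: one master seed; the PSA draw table is generated up
  front, so per-run results are independent of execution order.
- **Exact null**: a constant relative-risk vector short-circuits the PIF to
  exactly 0 (both distributions carry unit mass), so null interventions
  propagate to *bit-exact* zero QALY gain and a net cost equal to the
  campaign cost; `shift_distribution` with zero effect or reach returns its
  input unchanged for the same reason.
- **Beta fitting**: pathway distributions are fitted with the mean pinned
  to the central value and the concentration solved by least squares on the
  2.5%/97.5% quantiles. Not every (central, lo, hi) triple is exactly
  representable — for (0.779, 0.70, 0.83) the residual quantile error is
  ≈0.012 — so the achieved quantiles are returned alongside the fit.
- **Effect-size truncation**: normal effect draws are truncated at 0 by
  resampling, preserving the shift operator's non-negativity precondition;
  the truncation count is reported.
- **ICER quadrants**: the acceptability curve uses the net-monetary-benefit
  rule $\lambda\,\Delta Q - \Delta C \ge 0$ rather than "ICER below
  threshold", which misorders cost-saving (negative-ICER) and dominated
  runs. `compute_icer` flags cost-saving, dominated and undefined cases
  instead of returning misleading ratios.
- **Terminal age**: all cohorts are extinct by age 110; mortality 1 is a
  legal rate (used for the terminal cycle), and clipping is only counted
  when the feedback adjustment pushes a rate out of range.
- **Precision**: CSV exchange writes 17 significant digits so a written
  bundle reproduces model results bit-exactly; every table carries a schema
  version header.

## Design choices that were open

- **Diabetes as a risk factor for CHD/stroke**: the source family of models
  accounts for it, but publishes no functional form. The optional
  prevalence-driven incidence multiplier was *not* implemented: its only
  supportable default is "off", which would make it permanently dead code.
  The five disease tables are therefore independent.
- **Lag-window weighting**: uniform over inclusive integer offsets, as
  discussed above.
- **Costing attribution**: "subsequent-year" person-time is prevalence at
  the start of a cycle (which excludes that cycle's incident cases, costed
  at the first-year rate); last-6-months costs attach to disease deaths in
  their year of death.
- **Reporting**: stratum results are expressed per 1000 population, age
  groups follow the <40 / 40–60 / 60–80 convention by age in the base year,
  and group-level ICERs spread the campaign cost evenly over the eligible
  population.

## Limitations

Beyond the synthetic-world caveat: the model assumes disease independence
(no comorbidity interactions), a health-system cost perspective only (no
productivity or societal costs), homogeneous intervention response across
strata (differential gains arise solely from underlying epidemiology and
activity levels), no within-year time resolution, and no repeat campaigns.
The respiratory and injury pathways of the wider model family are out of
scope — the engine accepts an arbitrary disease list, but only the five
physical-activity-related diseases are parameterised.
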