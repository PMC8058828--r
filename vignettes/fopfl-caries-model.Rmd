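---
title: "Modelling caries impacts of front-of-package food labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling caries impacts of front-of-package food labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopflcaries)
```

## The model

`fopflcaries` implements a decision-analytical microsimulation of what a
front-of-package food-labeling (FoPFL) policy would do to dental caries and
its economic burden in an adult population, stratified by sex and six age
bands (15–18 through 65–80 years). The comparison is always labeling versus
status quo.

The disease model has two health states, *no caries* and *caries*. Every
individual starts caries-free. In each yearly cycle an individual develops
at least one new lesion with the stratum's annual incidence probability;
the lesion is diagnosed at the next dental visit and restored, returning
the individual to the no-caries state within the same cycle. Two
consequences follow that shape everything downstream:

* cycles are independent Bernoulli trials, so at most one lesion is counted
  per person-year, and
* the expected lesion total of a closed cohort has the closed form
  $n \cdot T \cdot p$ (`cohort_expectation()`), which serves as the
  analytic oracle for the stochastic engine.

The policy enters through a single behavioural parameter: labeling reduces
added-sugar intake by a fraction $e$ (default $0.066$, with deterministic
sensitivity bounds $0.044$ and $0.088$), identically in every stratum and
constantly over the whole horizon. A dose-response slope $s$ converts the
absolute intake reduction $\Delta g = e \cdot g$ (g/day) into a lower
annual incidence,

$$p_{\text{labeling}} = \operatorname{clamp}\!\left(p - s\,\Delta g,\; 0,\; p\right),$$

so the labeling incidence never exceeds the baseline and responds linearly
until the zero clamp. The exact functional form of the published
dose-response is not reproducible from the main text; the linear
absolute-risk form was chosen because the published deterministic
sensitivity results bracket the base case almost exactly symmetrically,
which is what a linear response produces. A relative-risk form,
$p \cdot (1 - s\,\Delta g)$, is available behind
`intervention_params(dose_response = "relative")` as a robustness check.
The slope's units (probability per g/day) are a declared convention of this
package; the baseline incidence is taken to already correspond to baseline
intake, so only the labeling scenario is adjusted.

Prevented lesions are valued three ways:

* **Treatment costs** — one single-surface restoration per lesion at unit
  cost EUR 74.10 (base case). Presets derived from published alternative
  scenario totals are shipped in `unit_cost_presets`: EUR 118.11
  (patient copayments) and EUR 148.73 (restoration failures), both obtained
  as scenario cost totals divided by the lesion total and labelled as
  derived values.
* **DALYs** — each lesion contributes
  $p_{\text{sympt}} \times \text{duration} \times \text{dw}$ DALYs.
* **Productivity losses** — DALYs times GDP per capita (Commission on
  Macroeconomics and Health approach), default EUR 40,332.

Person-level totals are scaled by `population / n_individuals` to the
reference population of each stratum, and the total row is the exact sum of
the stratum rows.

## Calibrated default parameters

The component values behind the per-lesion DALY are not published in the
main analysis; only the aggregate outcomes are. The defaults are therefore
calibrated stand-ins chosen once from the published totals:

* per-lesion DALY $= 677.62 / 2{,}370{,}715 = 2.8583\times10^{-4}$, split
  as disability weight $0.010$ (the GBD convention for symptomatic caries),
  symptomatic proportion $0.28583$ and duration $0.1$ years — each
  independently configurable;
* GDP per capita $= \text{EUR } 27.33\text{M} / 677.62 \approx
  \text{EUR } 40{,}332$ per DALY.

These reproduce the published DALY and productivity arithmetic to two
decimals; they are consistency-calibrated, not sourced component values.

## Discounting and the reporting convention

Costs and health outcomes are discounted at 3% per year with the
year-1-undiscounted convention, $(1+r)^{-(y-1)}$ (the published analysis
does not state its exponent convention; year-1-undiscounted is the common
one in health-economic evaluations, and no half-cycle correction is
applied since events are counted at year end).

Every internally consistent row of the published results table satisfies
*costs = lesions × 74.10* exactly at the printed precision, which is only
possible if lesions and costs receive identical (or no) discounting. The
reporting layer therefore defaults to the identity-preserving convention —
headline lesion counts and costs undiscounted, with the discounted
variants carried alongside in every result object and CSV export. Two rows
of the published table (women 51–64 and women 65–80) violate the identity;
`verify_reference_identities()` recomputes every row and flags exactly
those two, and they are excluded from any numeric matching.

## The synthetic input generator

The true inputs — survey added-sugar intakes, registry incidences, stratum
population sizes — are not published with the analysis. The generator
(`synthetic_spec()`, `synthetic_strata()`) creates German-like stand-ins
with the qualitative structure the analysis describes, so the whole
pipeline runs and is testable without any external data:

* female intakes are drawn uniformly in
  $[\min,\; \max/\text{male\_excess}]$ and assigned to age bands following
  the rank order of the age profile; males are the female value of the same
  band times `male_excess`. By construction every intake lies inside
  `sugar_range`, males exceed females within each band, intake falls across
  the first five age bands, and the extremes land on males 15–18 (maximum)
  and females 51–64 (minimum) — the consumption pattern reported for
  Germany. The default profile has a small uptick in the oldest band,
  which is what makes the 51–64 band, not 65–80, the minimum;
* incidences are drawn uniformly in `incidence_range`
  (default $[0.08, 0.30]$, a plausible adult annual caries risk range);
* population is a constant `population_scale` per stratum
  (default $10^6$, the order of magnitude of German age bands). Population
  size only scales outputs linearly, so any synthetic population-scaled
  total is illustrative, never a national estimate.

What passing tests on synthetic inputs do show: the engine, valuation
chain, discounting, scaling, and sensitivity machinery are correct and
internally consistent. What they cannot show: agreement of absolute totals
with the published national figures, which depend on the unpublished
inputs. The acceptance surface accordingly combines arithmetic identities
among published numbers with property-based checks of the machinery.

## Random numbers, reproducibility and variance reduction

All randomness flows from one master seed through a deterministic stream
derivation (`derive_seed()`, a 32-bit mixed congruential hash of the seed
and the stratum/scenario/run identifiers), so any stratum, scenario or PSA
run can be replayed in isolation and whole analyses are bit-reproducible.
The generator and engine save and restore the caller's RNG state.

Baseline and labeling scenarios are simulated with common random numbers
by default: the same uniform draw per individual-year is thresholded
against both probabilities, so the labeling count can never exceed the
baseline count in any year of any run. This makes incremental effects
noise-free in sign and is the reason monotonicity of outcomes in the
labeling effect holds run by run, not just in expectation. The published
analysis is silent on this point; CRN is a documented deviation knob
(`sim_controls(common_random_numbers = FALSE)` uses independent streams).

## Sensitivity analyses

* **Deterministic** (`run_dsa()`): the pipeline is re-run at alternative
  labeling-effect values (default $0.044, 0.066, 0.088$) with identical
  streams, so differences between rows are attributable to the effect size
  alone.
* **Probabilistic** (`run_psa()`): per run, the stratum incidences, the
  labeling effect, the dose-response slope and the unit cost are drawn from
  independent normal distributions with sd = 20% of the mean — the stated
  convention for the unit cost, adopted for all drawn parameters since
  their sds are not published, each overridable via `psa_spec()`.
  Correlations among parameters are not modelled (none are published).
  Draws are truncated to their domains by rejection sampling, with a clamp
  to the nearest bound after 1,000 rejected rounds (unreachable for means
  inside the domain at these sds). Each run simulates the two
  extreme-consumption strata (all twelve with `all_strata = TRUE`) and
  contributes one point to the cost-effectiveness plane: discounted
  incremental lesions prevented on the horizontal axis, discounted
  incremental cost on the vertical (savings negative, so the preferable
  quadrant is the bottom-right). Points exactly on an axis count toward the
  positive-effect and cost-saving sides; quadrant fractions sum to one by
  construction.

At full scale the published setup is 2,000 runs of 500,000 individuals per
stratum. The package's own routine checks run a scaled-down PSA of 200
runs × 20,000 individuals, which finishes in seconds and already pins the
bottom-right fraction at 100% under the default uncertainty specification:
with CRN inside each run, the incremental effect is positive whenever the
drawn effect and slope are positive, and at sd = 20% of the mean a
non-positive draw is a five-sigma event that the truncation excludes
entirely.

## Numerical and degenerate-input choices

* Incidence 0 and 1 are valid and exact (no lesions / a lesion every
  person-year).
* `adjusted_incidence()` clamps to $[0, p]$; equality with the baseline
  holds iff $s\,\Delta g = 0$.
* Undiscounted costs are computed as `lesions_prevented * unit_cost`
  directly, so the table identity holds to machine precision rather than to
  floating-point summation order.
* Tie-breaks in `extreme_strata()` use canonical order (males first, age
  ascending): maximum takes the first tied stratum, minimum the last, so an
  all-equal table yields the first and last stratum.
* Config files are written with 17 significant digits so a
  write-then-read round trip reproduces every double exactly; unknown keys
  are rejected to catch typos.

## Problem sizes used in the routine checks

The test suite and the reproduction script use deliberately small
simulations — 2,000–50,000 individuals per stratum and a 200-run PSA —
chosen so the whole suite completes in well under a minute while keeping
Monte-Carlo error far below every asserted tolerance (the binomial
standard error enters each assertion explicitly). The full published scale
(500,000 individuals, 2,000 runs) is available by changing
`sim_controls()` and `psa_spec()` defaults back up.

## Known limitations

* One single-surface restoration per lesion; no surface bookkeeping,
  restoration-failure cascades, or differential attack after prior caries.
* No mortality, migration or ageing between strata over the 10-year
  horizon; each stratum is a closed cohort (whether the original analysis
  refreshed entrants is not stated; a closed cohort is assumed).
* Long-term sequelae such as tooth loss are not converted to DALYs, so
  DALY and productivity figures are conservative.
* Implementation costs are carried as a pass-through range
  (EUR 5.29–9.56M) and never netted against savings; relabeling and
  campaign costs are out of scope.
* Synthetic inputs reproduce structure, not national values; absolute
  totals from the default configuration are illustrative.
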