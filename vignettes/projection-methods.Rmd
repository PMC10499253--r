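---
title: "A two-world cohort projection of treatment impact in sickle cell disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-world cohort projection of treatment impact in sickle cell disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdproj)
```

## The question the model answers

Sickle cell disease (SCD) causes chronic haemolytic anaemia and, over a
lifetime, end-organ complications — stroke, pulmonary hypertension (PH),
chronic kidney disease (CKD) — and early death. A haemoglobin-raising
disease-modifying treatment (an HbS polymerisation inhibitor) increases Hb
by about 1 g/dL in responders, and meta-analytic evidence links a 1 g/dL Hb
increase to sizeable relative risk reductions for these outcomes. `scdproj`
asks the population-level question: if such a treatment launches in 2023 and
diffuses through the eligible French SCD population, how many deaths,
strokes and chronic-complication cases are averted, and how many life-years
gained, by 2043?

The machinery is a *sequential multi-cohort* model: a prevalent cohort at
inception plus yearly incident cohorts, advanced one year at a time with
deterministic expected-value arithmetic (no Monte Carlo anywhere in the
projection). Two counterfactual worlds are run on identical parameters —
one where the treatment exists, one where it does not — and the impact is
their difference. `compare_worlds()` is the entry point; everything it needs
sits in a single validated parameter bundle (`base_case()`, overridable from
a flat YAML config via `load_config()`).

## Population dynamics

The base case starts with 6,100 prevalent patients (mean age 26.8 years) and
adds an incident cohort each year, starting at 300 patients and growing 5%
per year. **Entrant cohorts arrive for the first six years only (2023-2028).**
The descriptive text around the source tables could be read as entrants
arriving for all twenty years, but the published ledger decides the
question: with six cohorts the untreated world accumulates ~143,500
life-years and ~1,393 deaths, within 2% of the published 146,225 and 1,420,
while twenty years of entrants overshoot both by more than 30%. The
twenty-year reading remains available (`engine.entrant_years: 20`).

Entrants arrive at the start of a year and experience that year's full risk.
Each cycle removes deaths first, then draws complication incidence among
survivors; life-years accrue with half-cycle correction (`alive - deaths/2`).
Age is carried as a descriptor; hazards are age-invariant because no
age-specific rates are given — the one functional use of age is seeding the
baseline prevalent pools (below).

## Mortality

No annual death rate is given directly, and the published life expectancy at
birth (55 years), the "lifetime" life expectancy (30.8 years) and the death
counts are mutually inconsistent: no constant hazard reproduces all three.
The reproducible anchor is the crude death rate implied by the published
ledger — cumulative deaths over cumulative life-years, 1420/146225 = 0.971%
per person-year. `calibrate_mortality()` root-solves the full engine so the
untreated world hits that crude rate exactly, giving a baseline hazard of
about 0.00966/year. Calibration is lazy: any bundle whose hazard is `NA` is
calibrated on first use.

## Treatment uptake

Uptake is a sigmoid adoption-and-diffusion process with a 70% peak market
share and a three-year time-to-peak. Two sources are implemented:

* **Explicit schedule (default).** The treated-patient counts
  305, 1308, 3358, 4857, 5473, 5803 for 2023-2028. These are the only
  unambiguous uptake ground truth (the logistic's shape parameters are not
  published, and the published 2028 coverage of 76.7% exceeds the stated 70%
  peak). After 2028 the implied treated *share* is held constant, matching
  the plateau of the published diffusion curve.
* **Parametric logistic.** `logistic_share()` with `fit_uptake_anchors()`,
  an exact two-point inversion (or logit-scale least squares for more
  anchors) through the share anchors 5.0% at launch and 50.5% two years in,
  capped at the peak share.

Two share denominators coexist, and `build_schedule()` reports both: the
launch-year share is exactly 305/6100 = 5.0% against the population before
that year's entrants (`share`), while the engine exposes everyone alive —
entrants included — to risk, so its effective `coverage` is slightly lower.
Treated patients stay treated until death; new incident patients are treated
at the prevailing share in their entry year.

When the peak share is perturbed in sensitivity analysis, the schedule
counts scale proportionally (`peak_share / 0.70`): the counts realise the
base uptake assumption, so varying the assumption varies them. A consequence
worth knowing: because the default schedule anchors *counts*, perturbing the
population size changes coverage, which makes population size itself an
influential sensitivity parameter.

## Haemoglobin response

`simulate_responses()` draws the change from baseline in Hb for 1,000
patients from Normal(+1.1, 0.40) g/dL — the trial mean change at the
licensed dose, with the stated dispersion treated as a patient-level SD.
Patients are binned at 0.8 and 1.0 g/dL into non-responders, partial
responders and full responders (boundary values fall in the closed middle
bin; no continuous draw hits a boundary with measurable probability).

The projection itself uses the fixed reference split 18.0% / 19.5% / 62.5%
(`response_source: "printed"`) rather than a fresh simulation, so results do
not wobble with the seed: that split is one realisation about 1.7 standard
errors from the analytic normal fractions (22.7% / 17.5% / 59.9%,
`analytic_fractions()`). Both alternatives are exposed, and a property test
checks that a million simulated draws reproduce the analytic fractions to
within 0.005. What the generator emulates is the marginal distribution of
achieved Hb change at a fixed assessment time; it does not model
longitudinal trajectories, waning response, or adherence — real-world
response heterogeneity is folded into the three bins.

## From lifetime prevalence to annual risk

Lifetime complication prevalences (stroke 12.9%, PH 49.0%, CKD 26.6%) are
annualised over the 55-year life expectancy at birth under the
constant-hazard convention `r = 1 - (1 - P)^(1/L)`
(`annualize_lifetime_prevalence()`), which round-trips exactly; the linear
convention `P/L` is available behind a flag and differs by under 4% at
these prevalences.

The protective effect is response-stratified. A logistic attenuation curve
(`rrr_multiplier()`, midpoint 0.9 g/dL, steepness 25 per g/dL) maps achieved
Hb change to the realised fraction of the maximum effect, replicating the
step-like published effect curves: at +0.8 g/dL less than 8% of the effect
is realised, at +1.1 g/dL more than 99%. Bin representatives are 0.9 g/dL
(the curve midpoint, hence exactly half the effect) for partial responders
and 1.3 g/dL for full responders (where the multiplier equals the tabulated
relative risk to within 1e-3); non-responders get no effect.

Two semantic readings of the tabulated per-outcome values (death 0.36,
stroke 0.59, PH 0.43, CKD 0.47) were possible, and the package settles it by
feasibility. Read as *risk reductions* (multiplier `1 - 0.36` for death),
the largest achievable death reduction is `0.36 x 0.82 = 29.5%` even at full
coverage with every responder at maximum effect — short of the ~39%
benchmark the model must reach. Read as *risk ratios* (multiplier 0.36), the
benchmark is attainable. `risk_ratio` is therefore the default, with
`risk_reduction` available in config; an acceptance test asserts the
infeasibility of the alternative.

## The mortality channel

The same feasibility logic forced one further structural decision. With the
death risk ratio response-stratified like the morbidity channels, the
maximum annual death reduction is `0.4624 x coverage`; at the schedule's
ceiling coverage (~74%) that caps cumulative deaths averted near 34%, again
short of the ~39% benchmark. The default therefore applies the full death
risk ratio to **all treated patients** (`death_effect: "population"`),
which is also clinically coherent: the mortality benefit of reduced
haemolysis need not be gated on crossing an Hb threshold. The
response-stratified mortality channel remains available
(`death_effect: "stratified"`).

The trade-off is visible in the tornado: under the population-level channel
the deaths metric is insensitive to the Hb mean change (its published
runner-up position in the deaths tornado cannot be reproduced), while the
morbidity tornados match the published orderings. The two published facts —
the base-case death reduction and the deaths-tornado ranking — are not
simultaneously attainable under either channel; the package prefers
base-case fidelity and documents the residual.

## Complication states

PH and CKD are absorbing prevalent states (no remission, and a person can
hold both); stroke is a recurrent countable event with no state. Prevalent
pools are depleted by the same effective death hazard as everyone else
(complications feed no excess mortality back — the channels are
independent). At inception the pools are **seeded with age-accumulated
risk**, `N0 * (1 - (1 - r)^mean_age)`: a 26.8-year-old cohort whose lifetime
PH prevalence is 49% already contains ~1,700 prevalent PH cases. Seeding is
what makes the published prevalent-case and incident-case levels land
together (prevalent PH in 2043 exceeds twenty years of incident cases — only
possible with a starting pool); entrant cohorts arrive complication-free.
The published *percent impacts* on prevalent cases (about -26%) are not
reproducible under any pool accounting consistent with the published
incident impacts (a with-world pool cannot shrink by more than the incident
reduction plus its own extra survival), and the engine reports its own
consistent figures there.

## Life expectancy

"Lifetime" life expectancy is within-horizon person-years per member of the
inception-plus-entrant population, plus an extrapolation for horizon-end
survivors. The default credits survivors with `1/hazard` remaining years at
the **baseline** hazard in both worlds — the treatment effect is confined to
the horizon, the conservative standard choice. Extrapolating at each world's
own effective hazard is available (`extrapolation_mode:
"effective_hazard"`), as is truncation (`"none"`). None of the three
reproduces the published life-expectancy row (30.8 vs 35.7 years): that row
implies ~16 remaining years for 2043 survivors, which no reading of the
calibrated hazard (~0.97%/year, i.e. ~103 remaining years) or the stated
life expectancy at birth yields. Similarly, the published life-years-gained
figure implies about 4.7 within-horizon years per averted death, almost
exactly half of what any accounting that lets survivors keep living
produces (~9.4 years, deaths averted being centred around 2033); the
package keeps the coherent accounting and flags both rows as irrecoverable.

## Sensitivity analysis

`one_way()` moves a single parameter to its low and high bounds — printed
table brackets where available, otherwise +/-25% — and re-runs both worlds;
`tornado()` does this for every registered parameter (about twenty) and
ranks by impact spread, ties broken lexicographically. Perturbing the Hb
response parameters switches the response fractions to the analytic source
(a fixed printed realisation cannot respond to a parameter change);
perturbing the crude-rate target triggers recalibration; perturbing one age
fraction relaxes the sum-to-one invariant, with the mean age recomputed from
renormalised weights. Perturbation never mutates the input bundle — a
property test asserts the bundle and base comparison are bit-identical after
a full tornado.

## Numerical choices and problem sizes

The engine is linear algebra on scalars: one pass per year, exact
conservation of persons each cycle (`alive_end = alive_start - deaths`), and
a dominance property (treated-world events never exceed untreated-world
events while multipliers are at most 1). A two-world comparison including
calibration runs in well under a second. The test suite exercises the
documented closed forms (geometric survival, logistic inversion,
annualisation round-trip to 1e-12), a two-year hand-computed ledger matched
to 1e-12, convergence of simulated response fractions at n = 1e6, and
linear scaling of all counts in population size. Calibration uses `uniroot`
to a crude-rate tolerance of 1e-10; rounding happens only in the writers
(`write_results()`), never inside the engine.

## Worked example

```{r example, eval = FALSE}
library(scdproj)

params <- calibrate_mortality(base_case())
cmp <- compare_worlds(params)
cmp$comparison          # the ten headline metrics, both worlds
glance(cmp)             # one-row summary
autoplot(cmp)           # side-by-side counts
tornado(params, "deaths")
```

## Known limitations

* Four complications only; vaso-occlusive crises, leg ulcers, acute chest
  syndrome and end-stage renal failure are out of scope, as are costs and
  any discounting or quality-adjustment of life-years.
* Hazards are age- and sex-invariant; the age mix and female fraction are
  descriptors.
* No treatment discontinuation state and no competing market entries; the
  uptake plateau is held flat to the horizon.
* Relative risks are applied as if hazards were proportional, to rates
  derived from lifetime prevalence under an assumed fixed life expectancy —
  the weakest links in the evidence chain, and the reason the tornado
  exposes every one of those parameters.
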