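---
title: "A daily-cycle Markov model of watchful waiting after epinephrine autoinjector use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A daily-cycle Markov model of watchful waiting after epinephrine autoinjector use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiwait)
```

## The decision problem

Children with food allergy who use an epinephrine autoinjector (EAI) for a
severe reaction have traditionally been transferred to an emergency
department (ED) for observation even when symptoms resolve promptly. The
alternative — *watchful waiting* at home, with transfer reserved for
patients without an EAI and for biphasic (recurrent) reactions — avoids most
ambulance runs and ED visits but plausibly carries a higher out-of-hospital
fatality risk, since recurrence is then managed without clinical backup.
`epiwait` quantifies this trade-off as a cost–utility analysis for the
Canadian healthcare system: incremental costs (2022 CAD), incremental
quality-adjusted life years (QALYs), the incremental cost-effectiveness
ratio (ICER), and the incremental net monetary benefit (INMB) at a
willingness to pay (WTP) of \$50,000/QALY.

## Model structure and assumptions

The cohort starts fully in the *no severe reaction* state at age 1 and is
propagated deterministically in **daily cycles** for 20 years
(20 × 365 = 7,300 cycles; a year is fixed at 365 days, with no calendar or
leap handling, and age advances every 365 cycles). Daily cycles fit the
transient clinical course: a reaction, an ED visit, and a hospital stay are
each one-day events here, not persistent conditions.

States and transitions:

* **no_reaction** — daily probability of a severe reaction converted from
  the 0.087 annual risk; remission at the daily conversion of 0.058 per
  year while age is 1–6 inclusive (six annual exposures,
  (1 − 0.058)⁶ ≈ 0.70 of the allergic cohort still allergic at age 7, i.e.
  a 29–30% cumulative remission, consistent with the input source); daily
  all-cause mortality from the life table at the current integer age.
* **ww_reaction** (home observation day) — entered only under watchful
  waiting, by the 86% of reactions not transferred. Carries the derived
  per-day out-of-hospital fatality (below); survivors return home the next
  day. Biphasic reactions are *not* modelled as a 72-hour tunnel: they are
  folded into the 14% immediate-transfer fraction (0.094 without an EAI
  plus 0.046 biphasic), which matches the state diagram (no tunnel states)
  and keeps the ED-visit probability a simple sum.
* **ed_transfer** — admission to hospital with probability 1.68 × 10⁻³,
  otherwise home next day.
* **hospitalization** — one additional day; fatality per admission
  4.5 × 10⁻³.
* **remission** — absorbing for allergy (no further reactions, reduced
  annual cost, higher utility); background mortality still applies.
* **fa_death**, **all_cause_death** — absorbing.

All-cause mortality applies from *every* alive state, including the one-day
reaction states; at pediatric mortality rates (~10⁻⁴/year) this choice is
numerically invisible, but it keeps rows exactly stochastic. Competing
risks within a day are resolved by allocating food-allergy fatality first,
then background mortality on the survivors, then the remaining mass across
destinations; with daily probabilities of order 10⁻⁴ the ordering is
irrelevant at far below the reporting precision (the tests assert row sums
to 1 within 10⁻¹²). No half-cycle correction is applied: with daily cycles
the correction is bounded by half a day of rewards, i.e. ~\$3 and
~10⁻³ QALYs undiscounted over 20 years, the same order as the convention
choices it would interact with.

### Derived parameters

Three inputs are arithmetic consequences of others and are re-derived
whenever any raw input changes (sensitivity analysis, probabilistic draws,
config overrides):

* **ED-visit probability under watchful waiting**
  `min(1, p_no_eai + p_biphasic)` = 0.14.
* **Immediate-arm epinephrine cost** \$0.80 in-ED injection +
  0.54 × \$95 expected pre-ED autoinjector = \$52.10. Under watchful
  waiting, ED arrivals instead pay a mixture: the no-EAI fraction only the
  \$0.80 injection, the biphasic fraction a replacement EAI plus the
  injection (\$95.80), weighted 0.094 : 0.046.
* **Out-of-hospital fatality per watchful-waiting day.** The model is
  anchored to an overall annual food-allergy fatality of 6.9 × 10⁻⁷ and
  the assumption that watchful waiting multiplies it tenfold. The per-day
  risk q in the home-observation state solves

  target = multiplier × 6.9 × 10⁻⁷
         = q × (expected WW days/person-year) + in-hospital component,

  where the in-hospital component is
  0.087 × 0.14 × 1.68 × 10⁻³ × 4.5 × 10⁻³ ≈ 9.2 × 10⁻⁸ and the expected
  watchful-waiting exposure is 365 × (daily reaction probability) × 0.86
  ≈ 0.078 days/person-year. Annualized, 1 − (1 − q)³⁶⁵ ≈ 0.031. The
  derivation is inverted in a property test: recomposing total fatality
  from q always returns multiplier × target to 10⁻⁹ relative tolerance.

The ED-to-hospital admission probability deserves a note. It is defined by
a calibration — admission probability × in-hospital fatality must equal the
overall fatality under universal transfer — whose algebraic solution is
6.9 × 10⁻⁷ / (0.087 × 4.5 × 10⁻³) = 1.76 × 10⁻³, while the tabulated input
value is 1.68 × 10⁻³. Both are supported:
`calibrate_hospitalization_prob()` returns the solve, but
`default_parameters()` uses the tabulated 1.68 × 10⁻³, because the input
table defines the base case. The ~5% gap propagates only to quantities of
order 10⁻⁷/year and is far inside every reported tolerance. Consequently
the immediate-transfer arm's annual fatality is 0.087 × 1.68 × 10⁻³ ×
4.5 × 10⁻³ ≈ 6.6 × 10⁻⁷ rather than exactly 6.9 × 10⁻⁷.

All annual probabilities convert to daily scale by the constant-rate
compound formula 1 − (1 − p)^(1/365) (implemented with `log1p`/`expm1` so
the annual↔daily round trip is exact to machine precision), not the linear
p/365: the compound form is the standard constant-hazard assumption and is
what reproduces the 0.031 annualized out-of-hospital fatality from the
derivation above.

### Rewards, discounting, perspective

Annual state costs are spread uniformly (annual/365) over alive days;
baseline food-allergy costs accrue on reaction and hospital days too
(whether they should pause for those 1–2 days a year is undefined in the
inputs; accruing them uniformly changes totals by a few dollars over
20 years). The hospital day is priced once at \$1,866 — the mean 2.1-day
stay enters only the probabilistic distribution construction, keeping state
time and cost consistent. The 0.09 reaction disutility applies to each day
spent in any reaction-day state. Discounting is per-cycle,
(1.015)^(−t/365) from day 0. The societal perspective adds out-of-pocket
ED costs (\$95), productivity losses (3.6 h and 8 h at \$31.37/h, stored as
exact products 112.93 and 250.96 and rounded to \$113/\$251 only for
reporting), and annual out-of-pocket (\$2,577) and indirect (\$4,421)
food-allergy costs.

## Synthetic data and what the tests can show

Two generators make every stage testable without external downloads:

* `synthetic_life_table()` builds `q(age) = base_q × (1+growth)^age`
  tables (including all-zero mortality) for closed-form property tests.
* `synthetic_parameters()` draws full parameter sets from the probabilistic
  distributions, giving the property suite a family of valid non-base
  inputs.

The bundled 2022 Canadian life table (ages 0–25, both sexes) is a
transcription at pediatric precision, and is labelled synthetic in its
filename: absolute cost/QALY totals react only in the fourth significant
digit to life-table perturbations of this size, and incremental results are
essentially invariant because both strategies share background mortality.
The generators emulate the *distributional structure* of the inputs —
independent beta/gamma/lognormal draws — not features of real registry
data such as parameter correlation, age-dependent reaction risk, or
individual heterogeneity in reaction history and comorbidity; passing tests
therefore validate the model arithmetic and its Monte Carlo machinery, not
those clinical simplifications.

The cohort engine itself is cross-checked against an independent
microsimulation oracle (`microsim_cohort()`): 50,000 individuals stepped
day by day with direct categorical draws must match the deterministic trace
within three binomial standard errors state by state.

## Sensitivity and scenario machinery

* **One-way DSA**: each parameter to ±20% of base (at the rounding its
  source table reports, e.g. 0.070/0.10 for the severe-reaction
  probability and 0.74 for utility lower bounds; utilities are capped at
  1.0; the ED epinephrine cost spans its full logical range
  \$0.80–\$95). Dependent quantities are re-derived per bound — varying the
  biphasic probability moves the ED-visit split, and varying any fatality
  input re-solves q against the *unchanged* annual fatality target. Rows
  are ordered by ICER range (tornado order).
* **PSA**: 1,000 independent draws; beta for probabilities and utilities,
  gamma for costs interpreted as (shape, scale) — so Gamma(100, 8.5) has
  mean 850, matching the \$848 ambulance cost — and hospital daily cost as
  a gamma total divided by a Lognormal(0.25, 0.99) length of stay
  (meanlog/sdlog, mean ≈ 2.1 days). Distribution parameters are used
  exactly as tabulated even where their means sit a few percent off the
  base value (e.g. Gamma(100, 3.0) for the \$331 ED cost): the tabulated
  PSA column is taken as the specification of parameter uncertainty.
  Parameters marked fixed are not sampled; draws are independent (no
  correlation structure is given); derived fields are re-derived per draw.
  Point estimates use ratio-of-means (ICER of mean deltas), the standard
  cohort-CEA construction and the only one that stays finite when
  individual iterations have near-zero QALY deltas.
* **CEAC**: fraction of iterations with INMB > 0 per WTP. "Cost-effective"
  is defined through INMB rather than an ICER-threshold comparison because
  watchful waiting sits in the cost-saving/QALY-losing quadrant, where
  ICERs *above* the threshold favour it.
* **Scenarios**: 0% and 3% discounting, societal perspective, 100-, 500-
  and 1,000-fold fatality multipliers, start age 0 — each summarized over
  1,000 PSA iterations sharing one seed (common random numbers), matching
  the probabilistic construction of the reference scenario table. The base
  case is reported deterministically (the base-case table is labelled as
  such), with PSA means available alongside from `run_psa()`.

## Problem sizes and numerical choices

The default runs used throughout the package are 7,300 cycles per strategy
(two strategies per evaluation), 13 × 2 DSA evaluations, 1,000 PSA
iterations, 7 × 1,000 scenario iterations, and a 50,000-individual,
one-year microsimulation check; the daily trace loop is compiled (Rcpp), so
the full battery runs in a couple of minutes on a single core. Transition
rows are validated to sum to 1 within 10⁻⁹ at construction; traces must
conserve mass within 10⁻¹⁰ and stay nonnegative; zero QALY deltas are
reported as a dominance flag rather than a division error; seeds are
explicit arguments everywhere randomness enters (`run_psa`,
`run_scenarios`, `microsim_cohort`, `synthetic_parameters`) and identical
seeds reproduce results bit for bit.

## Known limitations

Hospitalization risk does not increase under watchful waiting (only
fatality does, via the multiplier); there is no individual heterogeneity
(comorbid asthma, prior biphasic reactions, EAI technique); remission is
permanent; EAI provision/education costs and travel time are outside both
perspectives; parameter draws are uncorrelated; and the life-table fixture
is a transcription, not an extract. These mirror the structural assumptions
of the analysis the package implements, and the scenario battery (notably
the 100–1,000-fold fatality multipliers) is the designed stress test for
the one assumption — excess fatality under watchful waiting — that the
evidence base cannot pin down.
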