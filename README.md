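# epiwait

Cost-effectiveness of **watchful waiting** versus **immediate emergency
department (ED) transfer** after epinephrine autoinjector (EAI) use for
severe food-allergic reactions in Canadian children.

Until recently, guidelines required every anaphylactic reaction treated with
an EAI outside hospital to be followed by an ED visit, regardless of whether
symptoms resolved. Watchful waiting — home observation after EAI use, with
transfer only for patients who lack an EAI or whose reaction recurs
(biphasic reaction) — avoids most of those visits at the price of a small
increase in out-of-hospital fatality risk. This package implements a
probabilistic Markov cohort model that quantifies that trade-off for the
Canadian healthcare system in 2022 Canadian dollars.

## Model

A cohort enters at age 1 in the *no severe reaction* state and is propagated
in **daily cycles over a 20-year horizon** through seven states:

```
no_reaction, ww_reaction, ed_transfer, hospitalization,
fa_death, remission, all_cause_death
```

Severe reactions occur at an annual probability of 0.087. Under immediate
transfer every reaction goes to the ED; under watchful waiting only the
fraction p_ED = 0.094 + 0.046 = 0.14 (no EAI, plus biphasic reactions)
transfers, the rest spend one day in home observation. ED visits admit to
hospital with probability 1.68 × 10⁻³; in-hospital fatality per admission is
4.5 × 10⁻³. The out-of-hospital fatality risk per watchful-waiting day is
derived so that total annual food-allergy fatality under watchful waiting
equals a 10-fold multiple of the overall annual fatality risk
(6.9 × 10⁻⁷/year), after subtracting the in-hospital component — an
annualized risk of 0.031 conditional on occupying the watchful-waiting
state. Remission (annual probability 0.058, ages 1–6) and age-specific
all-cause mortality from a bundled 2022 Canadian life table complete the
transitions.

Costs (2022 CAD) and utilities attach to states and entries: baseline annual
food-allergy costs, EAI replacement ($95), ambulance ($848), ED visit
($331), strategy-specific epinephrine costs ($52.1 blended in the immediate
arm), hospitalization ($1,866/day), utility 0.92 with a 0.09 reaction-day
disutility, 0.93 in remission. Costs and QALYs are discounted at 1.5%/year;
outcomes are the incremental cost, incremental QALYs, the ICER, and the
incremental net monetary benefit (INMB = WTP × ΔQALY − ΔCost) at a
willingness to pay of $50,000/QALY.

## Worked example

```r
library(epiwait)
params <- default_parameters()
lt <- bundled_life_table()
bc <- base_case(params, lt)
bc
#> Incremental comparison (comparator - reference)
#>   incremental cost:  $-1,154
#>   incremental QALYs: -0.0007302
#>   ICER:              $1,580,000/QALY
#>   INMB at WTP $50,000:  $1,117
#>   incremental food-allergy death risk: 9.2e-05
#>   cost per death prevented: $12,543,897
```

Watchful waiting saves about $1,154 per patient over 20 years while losing
7.3 × 10⁻⁴ QALYs — immediate ED transfer "buys" those QALYs at about
$1.58 million each, and prevents one food-allergy death per roughly
11,000 patients over the horizon at $12.5 million per death prevented.
Since ICERs far above the willingness-to-pay threshold indicate poor value
for the *more expensive* strategy, watchful waiting is cost-effective
(INMB ≈ +$1,117).

The full workflow lives in `analysis/`:

| script | what it does | output |
|---|---|---|
| `analysis/01_base_case.R` | deterministic base case | `results/base_case*.{csv,json}` |
| `analysis/02_dsa.R` | one-way sensitivity, tornado-ordered | `results/dsa_tornado.csv` |
| `analysis/03_psa.R` | 1,000-iteration PSA, CE plane + CEAC | `results/psa_*.csv` |
| `analysis/04_scenarios.R` | discounting, societal, fatality-multiplier and start-age scenarios | `results/scenarios.csv` |

In the probabilistic analysis every one of 1,000 iterations is
cost-effective at $50,000/QALY (acceptability 100% for willingness-to-pay
from $0 to $150,000), and the conclusion only reverses under extreme 500-
and 1,000-fold increases in watchful-waiting fatality.

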