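# glywalk

Simulating the acute effect of walking on the diurnal glucose curve, and
analysing the within-subjects study design built around that simulation.

## What this is for

Interactive glucose simulations are a behaviour-change technique for adults
with type 2 diabetes: show a person their own modelled 24-hour glucose curve,
let them explore what a walk of a chosen start time and duration would do to
it, and measure whether their *outcome expectancies* (beliefs about the
effect, elicited by asking them to draw the post-walk curve) and *intentions*
to walk change. `glywalk` packages the quantitative machinery of such a
study so it can be reproduced, stress-tested and extended without any
participant data:

- **Counterfactual curves** — for any HbA₁c in [5.9, 10.1] (step-free, with a
  43-curve bank at 0.1 steps), a 96-point diurnal glucose curve on a
  15-minute grid whose time mean is the estimated average glucose
  eAG = 28.7·HbA₁c − 46.7 mg/dl, with meal-associated excursions.
- **Walk simulator** — the walk produces a nadir drop
  D = max(0, (β₀ + β₁(G_pre − 100))·(dur/30) + ε) reached 30 min after the
  walk ends, with a linear return to the no-walking curve 6 h after the walk
  starts. AUC is the rectangle rule: sum of the 96 values × 15 (mg/dl×min).
- **Drawing scoring** — a drawn trajectory from 9 AM onward is spliced onto
  the counterfactual, resampled to the grid, and scored as the AUC decrease
  it implies (positive = expected improvement), with a reproducible
  extreme-drawing outlier rule.
- **Synthetic cohort** — a generator calibrated to the study's marginals
  (n = 1335; HbA₁c 7.3 ± 1.2 truncated to [5.9, 10.1]; expectancy
  12,265 ± 20,253 pre → 10,582 ± 19,117 post mg/dl×min; intentions
  5.16 → 5.47 on a 7-point scale with 25% post missingness; minutes
  67.1 → 100.5; 10.6% heavy-tailed "non-understander" contamination).
- **Analysis pipeline** — paired t tests, the difference-of-differences test
  of belief shift, a three-strategy missing-data sensitivity suite reporting
  the most conservative result, subset exclusion, and a study summary.

## Worked example

```r
library(glywalk)

crv <- build_curve(7.3)
crv
#> Diurnal glucose curve (HbA1c 7.3%)
#>   96 points, 15-min grid; mean 162.8 mg/dl, range [150.1, 204.1]
#>   AUC 234446 mg/dl x min

simulate_walk(crv, walk_plan(540, 30), noise = 0)   # 9 AM, 30 minutes
#> Walk simulation: 30 min starting 09:00 (HbA1c 7.3%)
#>   nadir drop 31.0 mg/dl; AUC reduction 5579 mg/dl x min

co <- generate_cohort(cohort_params(seed = 20251))
summarize_study(co)
#> Full sample (n = 1335)
#>   Outcome expectancy (AUC decrease): 12978 (21968) -> 11138 (20266) mg/dl x min
#>     shift toward simulation: 1839.8, t(1334) = 4.31, p = 1.75e-05
#>   Intention (1-7): 5.01 (1.53) -> 5.32 (1.35)
#>     gain 0.213, t(1334) = 5.91, p = 4.37e-09 [carry_forward]
#>   Minutes walking: 69.0 (92.5) reported -> 100.8 (96.0) planned
#>     gain 31.8 min, t(1334) = 11.84, p = 8.16e-31
#> Exclusions: 162 of 1335 (18 extreme on both drawings, 149 self-reported)
#> ...
```

Reading this: the time mean of the HbA₁c 7.3 curve is its eAG
(28.7 × 7.3 − 46.7 = 162.8 mg/dl). A deterministic 9 AM/30-minute walk for
that person removes 5579 mg/dl×min of glucose exposure (a triangle of gap
with 31 mg/dl nadir spread over 6 hours). In the synthetic cohort, drawn
expectancies start far more optimistic than the simulation (~13,000 vs
~5,700 mg/dl×min) and shift toward it after "using" it (difference of
differences ≈ 1840, t ≈ 4.3), while intentions and planned minutes both
rise — the structure the generator is calibrated to emulate.

A command-line wrapper over the same functions ships at
`inst/cli/glywalk.R`:

```sh
Rscript inst/cli/glywalk.R simulate --a1c 7.3 --start 09:00 --duration 30
Rscript inst/cli/glywalk.R run --seed 7 --out-dir out/
```

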