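---
title: "glywalk: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glywalk: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glywalk)
```

`glywalk` reproduces the quantitative core of a web-based behaviour-change
experiment for adults with type 2 diabetes: a personalised diurnal glucose
curve, an interactive simulation of the acute glycemic effect of walking,
a drawing task that quantifies outcome expectancies as an area under the
curve (AUC), and the within-subjects statistical analysis of the resulting
pre/post measurements. This vignette is the package's account of those
models: what is assumed, what is calibrated, and what the synthetic data
can and cannot tell you.

## The counterfactual curve

All trajectories live on a fixed grid of 96 points at 15-minute spacing
(00:00–23:45), and every AUC in the package is the rectangle rule
`sum(values) * 15` in mg/dl×min — deliberately *not* the trapezoid rule,
because the study arithmetic this package reproduces multiplies the
15-minute vector by 15. On this uniform grid the rectangle AUC equals
1440 × the time mean exactly, which makes several identities testable to
machine precision.

The "no walking" curve for a person with a given HbA₁c is

\[ G_0(t) = \mathrm{eAG}(A) + a(A)\,\big(s(t) - \bar s\big), \]

where eAG is the ADAG linear convention eAG = 28.7·A − 46.7 mg/dl, `s(t)`
is a sum of three Gaussian meal excursions (defaults: 08:00, 12:00, 18:00,
width 45 min) and `a(A) = 40 + 10 (A − 5.9)` mg/dl makes higher-HbA₁c days
both higher and more excursive. Subtracting the grid mean \(\bar s\)
anchors the curve's time average to the eAG exactly, so the curve bank is
clinically interpretable at every supported HbA₁c (5.9–10.1). The meal
times, widths and amplitudes are a reconstruction — the original study's
source curves are not published — so all of them are `curve_config()`
parameters; the shape was chosen for qualitative realism (fasting baseline,
postprandial peaks, return to baseline overnight) and because it keeps
\(\partial G_0 / \partial A > 0\) pointwise, giving a clean monotonicity
property (higher HbA₁c ⇒ higher curve everywhere, strictly larger AUC).

## The walking effect

A walk starting at time \(t_0\) with duration \(d \in \{15, 30, 45, 60\}\)
minutes opens a gap below the counterfactual: zero at \(t_0\), rising
linearly to the nadir drop

\[ D = \max\{0,\ (\beta_0 + \beta_1 (G_{\text{pre}} - 100))\,\tfrac{d}{30} + \varepsilon\},
   \qquad \varepsilon \sim N(0, \sigma_D), \]

at \(t_0 + d + 30\) (30 minutes after the walk *ends*; the alternative
anchoring at \(t_0 + 30\) is a config switch, since "30 minutes after
exercise" is ambiguous), then declining linearly back to zero at
\(t_0 + 360\): a conservative six-hour return to non-exercise levels. The
gap is additive; a multiplicative ("proportional") return is a defensible
alternative reading, but the additive triangle makes the AUC reduction
exactly \(\tfrac{1}{2}\cdot 360\cdot D = 180\,D\) when nothing truncates —
a closed form the tests exploit. A recovery horizon crossing midnight is
truncated (no wrap to the next day), matching the day-bounded drawing
window; glucose is floored at 1 mg/dl, which never binds under defaults.

**Calibration.** The predictive model behind the original simulation is not
published, so \(\beta_0, \beta_1, \sigma_D\) are calibrated analytically,
and the calibration is verified empirically by the acceptance tests: with
\(G_{\text{pre}}\) the 9 AM value of the
counterfactual, which is linear in HbA₁c, and HbA₁c a truncated normal
(parent 7.3/1.2 on [5.9, 10.1]), choose \(\beta_1 = 0.10\) mg/dl per mg/dl
as a plausible pre-glucose sensitivity, then solve

\[ 180\,\mathbb{E}[D] = 5712, \qquad 180\,\mathrm{SD}[D] = 2033 \]

for \(\beta_0 = 23.76\) and \(\sigma_D = 10.92\). These are the shipped
defaults; the targets are the cohort mean and SD of the simulated AUC
reduction for the 9 AM/30-minute walk.

## Scoring drawings

A drawn trajectory (time/glucose points from 9 AM on, not necessarily on
the grid) is spliced onto the counterfactual: counterfactual values before
9 AM, linear resampling of the drawn points within their span, a linear
bridge from the counterfactual's 9 AM value if the drawing starts late, and
a linear return from the last drawn point to the counterfactual's midnight
value (its 00:00 level — the curve is treated as day-periodic at that
boundary). Linear resampling is the simplest defensible reduction of a
free-hand trace to a 15-minute vector; no smoothing is applied. The
expectancy measure is `counterfactual AUC − drawn AUC`, stored with
expected improvements positive.

The extreme-drawing rule (`outlier_rule()`) flags a drawing whose implied
|AUC change| exceeds 50,000 mg/dl×min — roughly 25 standard deviations of
the simulated effect, and about the exposure change of a uniform
±55 mg/dl shift over the whole drawn window — or whose spliced curve
implies non-positive glucose. The published study excluded by three-coder
consensus, which cannot be replicated mechanically; the threshold is
configurable and the subset machinery does not depend on its exact value
because the generator marks its contaminated rows explicitly.

## The synthetic cohort

`generate_cohort()` emulates the study's *marginal* structure, one row per
participant, deterministically given a seed:

- **HbA₁c**: truncated normal, parent 7.3/1.2, bounds [5.9, 10.1] (the
  range the curve bank supports). The printed sample moments are treated as
  parent parameters; the realized truncated moments (≈7.54/0.94) are what
  the law-of-large-numbers tests check.
- **Simulated reduction**: each row's own 9 AM/30-minute walk, run through
  the simulator (a vectorised path verified against `simulate_walk` row by
  row).
- **Expectancies**: presimulation draws are Gaussian, 12,265/20,253
  mg/dl×min; postsimulation values shrink toward the row's own simulated
  reduction, `post = (1−w)·pre + w·sim + ε` — the hypothesised mechanism
  (beliefs shift toward what the simulation showed). Solving the printed
  pre/post/sim moments gives w = 0.2568 and SD(ε) = 11,775, the shipped
  defaults.
- **Contamination**: a 10.6% fraction (the complement of the published
  1194/1335 retained subset) gets independent Student-t noise (df 4, scale
  15,000 mg/dl×min) added to both drawings and `excluded_candidate = TRUE`.
  The noise is symmetric, so the full-sample expectancy means are
  preserved while the tails motivate the subset analysis.
- **Intentions**: a latent bivariate Gaussian (5.16/1.8 pre, +0.31 gain,
  1.6 post, correlation 0.5) clamped to the 1–7 scale. Clamping shifts both
  means down ≈0.14, leaving the realized gain ≈0.31; the exact printed
  moments and the hard range cannot both hold (no distribution on [1, 7]
  that a clamp produces has SD 1.8 at mean 5.16 after censoring), and the
  package keeps the range. Post-simulation intention is missing completely
  at random with probability 0.25 (reconstructed from the study's paired
  df of 1001 out of n = 1335).
- **Minutes walked**: gamma marginals matching the printed mean/SD exactly
  (67.1/88.0 reported, 100.5/100.4 planned) coupled by a Gaussian copula at
  the configured latent correlation. A clamped Gaussian would bias the
  means by >10 minutes at these coefficients of variation; the gamma is
  right-skewed with mass near zero, which is also what real
  minutes-per-week data look like.

The default within-person correlation (0.5) is a choice, not a published
value: the study prints no paired SDs or correlations, so generated *t*
statistics for intentions and minutes match the published ones only in
sign and rough magnitude, never numerically. That is why the pipeline's
accuracy claims attach to mean differences and to property-based
guarantees (oracle equivalence of the paired t, exact type-I error under
an exact null, CI coverage under an injected shift) rather than to
reproducing printed *t* values — which are themselves internally
inconsistent in the source (the same 0.31 intention gain is reported with
two different *t* statistics).

What passing tests therefore show: the arithmetic pipeline is exact, the
simulator and generator hit their calibrated first and second moments, and
the statistical procedures have their nominal operating characteristics on
data *of this synthetic form* (Gaussian cores, symmetric contamination,
MCAR missingness). What they do not show: robustness to the real data's
unknown dependence structure, non-MCAR dropout, or drawing artefacts
beyond the modelled heavy tails.

## The analysis pipeline

`paired_t()` is the classical paired t test written out
(t = mean(d)/(sd(d)/√n), df = n − 1, two-sided p), pairwise-deleting
incomplete pairs; it is verified against R's `t.test` to 12 significant
digits on random instances. A zero-variance difference vector is mapped to
t = 0, p = 1 (identical columns) rather than NaN. The
difference-of-differences test for belief shift runs the paired t on
(pre − sim) vs (post − sim); its mean difference equals
mean(pre) − mean(post) identically, so the simulation column affects power
but not the point estimate.

Missing-data sensitivity runs three strategies — complete case, mean of
observed post values (one reading of "mean imputation"; the grand-mean
alternative was rejected as mixing pre and post scales), and the
participant's own pre value carried forward (under which the imputed rows
contribute exactly zero difference) — and reports the *most conservative*,
operationalised as the smallest |t| since the source does not define the
term. Subset exclusion removes rows extreme on **both** drawings (a person
whose two drawings are both beyond the rule, as a one-off extreme drawing
is more likely a slip than a misunderstanding) or flagged as
self-reported non-understanders, with counts per (possibly overlapping)
reason. Two-sided p-values are used throughout.

## Determinism and problem sizes

One master seed fans out to per-module sub-seeds (`run_config()`), so an
end-to-end run is byte-reproducible and adding a stage never perturbs
another stage's draws. The test suite sizes its Monte-Carlo checks for
tightness at interactive scale: moment convergence at n = 50,000 against
3-standard-error bands, type-I error over 2,000 replicates of n = 100
cohorts under the exact null (zero shrinkage, where post = pre + noise;
the "zero intention gain" configuration is *not* an exact null because
unequal pre/post SDs interact with the scale clamp), and CI coverage over
500 replicates at the study's n = 1335. The calibration checks accept
within three Monte-Carlo standard errors of a single seed-fixed n = 1335
cohort, the scale at which the targets were defined.

## Known limitations

- The curve shape and the effect-model coefficients are reconstructions
  anchored to published summary statistics, not fits to glucose data; no
  insulin, meal-timing or multi-bout effects are modelled.
- The outlier rule is a mechanical stand-in for human-coder exclusion; the
  published subset cannot be replicated exactly.
- Generated t statistics for paired measures depend on an assumed
  within-person correlation (0.5) and should not be compared numerically
  to the published ones.
- The generator draws expectancy summaries directly; it does not simulate
  drawing traces point by point.
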