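---
title: "Modelling and analysing two-step confidence re-assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing two-step confidence re-assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metashift)
```

## The paradigm

In the two-step confidence paradigm an observer performs an ensemble
discrimination — which of two shape classes (Xs vs Os) predominates in a
7×7 array — and then rates confidence twice in a row on a 0–100 scale with
steps of 10, treated throughout as ten ordered levels {10, 20, …, 100}.
The second rating may not repeat the first, and a first rating at either
endpoint of the scale ends the trial with no second rating (an *extreme*
trial). Task difficulty is controlled by a two-up-one-down staircase on
the majority/minority element ratio, which converges on the ~70.7%-correct
point of the psychometric function.

The scientific question is whether re-evaluating one's confidence improves
*metacognitive* sensitivity — how well confidence tracks one's own
accuracy — and `metashift` provides both a generative observer that
simulates the experiment with known ground truth and the estimators used
to answer the question:

* **meta-d′** (maximum likelihood, equal-variance SDT) for the first,
  second, and trial-averaged confidence streams;
* **type 1 d′ split by shift direction** (up- vs down-shift trials);
* the **second-step metacognitive d′**: treat an up-shift as a "yes"
  report about one's own accuracy, so hits are correct trials followed by
  an up-shift and false alarms are incorrect trials followed by an
  up-shift, scored with d′ = Φ⁻¹(HR) − Φ⁻¹(FAR) and
  c = −½(Φ⁻¹(HR) + Φ⁻¹(FAR)), against a permutation-based empirical
  chance level obtained by shuffling the correctness labels.

## The generative observer

Each trial presents a ratio imbalance `i = 2·majority − 49`. The observer
draws evidence `x ~ N(±s·i/2, 1)` (sign by stimulus class, `s` the
sensitivity slope) and responds by the side of a criterion `c`. Confidence
report `j ∈ {1,2}` is based on `y_j = x + ε_j`, where `(ε₁, ε₂)` is
zero-mean bivariate Gaussian with SDs `σ₁`, `σ₂` and correlation `ρ` —
the metacognitive noise. Partial independence of the two draws
(`ρ < 1`) is the mechanism of interest: averaging two partially
independent reads reduces noise, and `σ₂ < σ₁` makes the re-evaluation
itself the better read.

Each report thresholds the *noise-normalised* criterion-relative evidence
`|y_j − c| / sqrt(1 + σ_j²)` through the ordered confidence criteria: the
observer is calibrated to the spread of its own confidence evidence. Under
raw (unnormalised) thresholding, a less noisy second read has smaller
absolute evidence on average, which would build a strong structural
down-shift bias into the generator; human cohorts show approximately
balanced up- and down-shifts and a second-step criterion near zero, so
calibration is the realistic choice.

Defaults (chosen once as the simulated study conditions):

| parameter | default | rationale |
|---|---|---|
| `sensitivity_slope` | 0.22 | d′ ≈ 1.09 at the 27:22 equilibrium ratio, i.e. ~70.7% correct, matching the staircase target |
| `meta_noise_sd_1` / `_2` | 1.0 / 0.5 | the re-evaluation is the less noisy read |
| `meta_noise_corr` | 0.4 | partially independent noise sources |
| `confidence_criteria` | `seq(0.2, 2.6, 0.3)` | nine thresholds for ten levels; yields ~15% extreme trials, near the share seen in human cohorts |
| `criteria_scale_2` | 0.9 | solved numerically so the default observer's expected second-step criterion is zero (no systematic up/down bias) |
| staircase start/floor/ceiling | 32 / 25 / 39 | floor is the smallest majority on 49 elements; ceiling keeps ten minority elements visible |

The no-repeat rule is enforced by nudging a colliding second rating one
level toward the raw second-evidence direction (ties nudge down) — a
forced re-evaluation with minimal distortion. The per-session random
stream is consumed in a fixed documented order (stimulus sequence, then
five draws per trial), so a (config, observer, seed) triple is fully
reproducible; cohort and permutation streams are fanned out from one
master seed.

What the generator does **not** emulate: individual differences under the
default single parameter set (human accuracy SEs are an order of magnitude
larger), confidence leak and other sequential dependencies, pointer-
position response habits, lapses of attention during confidence (only
type 1 lapses are modelled), and reaction times. Passing tests therefore
show that the estimators recover what this observer family generates, not
that human data will match any particular absolute value.

## Preprocessing and exclusions

`classify_shift()` labels each trial UP/DOWN/EXTREME; the three labels
partition every session. Exclusions follow the standard two-rule scheme,
in order: (1) participants whose type 1 accuracy lies more than 2.5
sample SDs from the group mean (mean and SD over all submitted
participants); (2) participants with fewer than 50 up-shift or fewer than
50 down-shift trials. Extreme trials are dropped from *all three* meta-d′
computations, not just the second-interval one, so the first/second/
averaged fits are computed on the identical trial set and differ only in
the confidence stream; including them in the first-interval fit is
defensible (the first rating exists) but would confound stream with trial
set.

## The meta-d′ fit

Counts enter as the 2×2×K stimulus × response × confidence-bin table.
`K = 5` by default: with ~360–380 usable trials per participant a 10-bin
table leaves many near-empty cells, and pairwise collapsing of adjacent
levels is the mildest grouping; K is configurable and always shared by the
three streams. Trial-averaged confidence produces half-step values; the
equal-width bins over (0, 100] absorb them unambiguously.

The fit holds the type 1 summary (d₁, c₁, edge-corrected) fixed and asks
what sensitivity `meta-d′` an equal-variance SDT observer would need, with
its type 1 criterion at the same relative position `c₁·meta-d′/d₁`, for
its confidence to reproduce the observed type 2 counts; `meta-d′` and the
2(K−1) type 2 criteria maximise the multinomial likelihood of confidence
conditional on stimulus and response.

Numerical choices: each of the 2K cells is padded with `1/(2K)` before
fitting (uniformly, for every stream and participant, so comparisons are
unbiased); criteria are parameterised as log-spacings away from the scaled
type 1 criterion, which enforces their ordering; optimisation is BFGS
restarted from three deterministic initialisations (meta-d′ at 0.5·d₁,
d₁, 1.5·d₁, criteria at empirical quantiles) with the best likelihood
kept; rates equal to 0 or 1 anywhere in the package are replaced by
`1/(2N)` and `1 − 1/(2N)`. A table whose ratings all fall in one bin
carries no type 2 information and returns meta-d′ = 0 with a warning
rather than an optimiser artefact. `fit_meta_d_fixed()` exposes the
criteria-only profile fit used to validate the optimiser against a
brute-force grid.

## The second-step statistic and its chance level

The observed second-step d′ is compared with an empirical chance level:
correctness labels are permuted across the participant's up/down trials
(shift labels fixed, so the overall up-shift probability is preserved),
d′ recomputed each time, and the null mean taken over 1000 permutations
by default (the count is a package choice; each participant gets a seed
derived from the master seed). The group test is a paired t of observed
d′ against per-participant null means; the per-participant permutation
p-value is also reported.

One subtlety the permutation framing makes visible: an observer whose
*second* rating is pure noise but whose *first* rating is informative is
**not** at chance on this statistic. The no-repeat paradigm couples
shifts to the first rating (a high first rating leaves little headroom to
shift up), and the first rating predicts accuracy, so up-shifts
anti-predict accuracy and the second-step d′ is systematically negative
(about −0.17 under the default parameters). The exchangeable null —
shifts carrying no information about accuracy — requires both reports to
be uninformative, and under that null the d′-vs-chance test rejects at
its nominal α (the calibration suite checks this on 20 simulated
cohorts). Interpreting a *negative* second-step d′ as "worse than chance
re-evaluation" is therefore not warranted without this control.

## Group statistics

`paired_t()` implements the paired t test with Cohen's dz and the 95% CI
explicitly (and is validated against the reference implementation);
`required_sample_size()` finds the minimal n by exact noncentral-t power
iteration — no normal approximation — and reproduces the canonical
planning example (dz = 0.62, α = .05, power = .95, one-sided → n = 30).
All seven cohort comparisons in `full_report()` are two-tailed by
default, while the power analysis is one-tailed; published t/p pairs in
this literature are consistent with two-tailed testing, whereas the
planning n matches the one-tailed computation, so both conventions are
exposed rather than reconciled. Descriptives report mean ± SE. No
multiple-comparison correction is applied, matching common practice for
this battery.

## Problem sizes and runtime choices

The test and validation suites use sizes chosen to give tight Monte-Carlo
error at desk scale: 10,000-trial runs (500-trial burn-in) for staircase
convergence, 20,000 trials for meta-d′ self-consistency and
information-destruction checks, 20-participant × 450-trial cohorts for
the qualitative effect battery, and 20 × 8-participant cohorts for null
calibration. The meta-d′ optimiser is validated against a 0.01-step
profile-likelihood grid on small tables.

## Known limitations

* Absolute meta-d′ values depend on the binning (K) and padding
  conventions, which published studies rarely report; only *within-study
  contrasts* between streams sharing K and padding are interpretable.
* The equal-variance SDT observer is the analysis model and the
  generator; model mismatch with human confidence (unequal variance,
  non-Gaussian noise) is not represented.
* The staircase's integer ratio steps quantise difficulty coarsely near
  the equilibrium (d′ jumps ~0.4 per element), so simulated asymptotic
  accuracy sits slightly above the nominal 70.7%.
* A cohort simulated from one parameter set understates between-subject
  variance; pass a list of `observer_params` to `simulate_cohort()` for
  heterogeneous cohorts.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(cohort_size = 12, seed = 2026)
res <- run_pipeline(cfg, out_dir = "run01")
res$report
```
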