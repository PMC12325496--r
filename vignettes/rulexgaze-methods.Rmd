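---
title: "Mixture modeling of judgment processes and looking-at-nothing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture modeling of judgment processes and looking-at-nothing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulexgaze)
```

## The problem

In multiple-cue judgment, people estimate a numeric criterion from a
stimulus's observable cues. Two qualitatively different cognitive processes
can produce such judgments: retrieving stored *exemplars* and weighting
their known criterion values by similarity, or applying an abstracted
linear *rule* over the cues. The two processes mimic each other over much
of a stimulus space and separate only where the rule extrapolates beyond
the exemplars' criterion range. `rulexgaze` implements the modeling and
gaze machinery needed to measure each participant's relative reliance on
the two processes and to relate it to *looking-at-nothing*: fixations on
the blank screen locations where exemplars were learned, a process-tracing
signature of exemplar retrieval.

## Task environment

The stimulus space is the 16-cell grid of two cues `x1, x2 ∈ {1..4}`. The
default criterion is the multiplicative function
`c = round(5/3 · x1 · x2 + 2)` (values 4–29 on the 1–30 response scale); a
linear-additive criterion is available through
`task_environment("additive")`. Rounding is *half away from zero*: no grid
value lands on .5, so the choice is inert on the grid, but it must be fixed
for arbitrary additive coefficients.

Four exemplars — `(2,1), (1,4), (3,2), (4,3)`, criteria 5, 9, 12, 22 — are
the default training set. This is the unique 4-set that contains `(2,1)`,
uses each cue value exactly once per cue, contains no symmetric stimulus
(each exemplar must have a distinct reversed-cue distractor), and leaves
the extreme stimuli `(1,1)` and `(4,4)` outside the exemplar criterion
range so that the test phase contains genuine extrapolation stimuli. The
set is overridable in `task_environment()` and via a YAML config.

Trial schedules reproduce the experiment's structure: location-training
blocks of 8 (four exemplars plus their reversed-cue distractors),
criterion-training blocks of 4, and test blocks of all 16 stimuli, with
seeded random order within blocks (8 test blocks = 128 trials). Training
termination rules (three consecutive error-free blocks, caps of 15/10
blocks) are schedule metadata, not simulated learning. The presentation-time
calibration is a 4-down-1-up staircase starting at 2000 ms with steps of
−336.60 / +400 ms; the staircase has no stated lower bound, so durations
are floored at a configurable 1 ms to stay positive.

## The RulEx-J model

The judged criterion blends a similarity and a rule prediction,
`ĉ = α·ĉ^Sim + (1−α)·ĉ^Rule`, with `α ∈ [0,1]` the person's relative
reliance on similarity. The similarity process is a generalized-context-model
style kernel over attention-weighted city-block distance,
`S(s,e) = exp(−h·d_w(s,e))`, normalized over the four exemplars; it can
only interpolate within the exemplar criterion range. The rule process
`β0 + β1·x1 + β2·x2` extrapolates freely. Responses are Gaussian around
`ĉ` with SD `σ`.

Design choices in the model surface:

* **Five free parameters.** α, β0, β1, β2, σ. The similarity sensitivity
  `h` is a *fixed* constant (default 1, configurable): the model is
  specified with exactly five free parameters, and the attention weights
  are derived rather than free.
* **Attention weights.** `w_m = |β_m| / (|β1| + |β2|)` — the rule's own cue
  weights, normalized; absolute values guard against negative fitted betas.
  If both betas are exactly zero the weights are undefined; equal weights
  `(.5, .5)` are substituted with a warning.
* **Likelihood.** A plain (untruncated, continuous) Gaussian. Truncation to
  the 1–30 scale is available behind `truncate = TRUE` but off by default:
  the plain Gaussian is the fitting model, and σ̂ stays interpretable in
  criterion units.

## Estimation

Per participant, the five parameters are estimated by maximum likelihood
with **leave-one-stimulus-out cross-validation**: one fold per distinct
stimulus (16 with the full grid), held-out set = all trials of that
stimulus. This fold construction makes the held-out score a true
generalization test across stimuli; a blockwise alternative would test
stability over time instead, which is not the question the cross-validation
answers here. Fold estimates are aggregated by the mean; the medians of the
cue weights are kept alongside because the gaze analyses use each
participant's normalized median cue weights as attention weights.

The optimizer is bounded L-BFGS-B with multiple starts: three deterministic
starts (OLS betas from `response ~ x1 + x2`, residual-SD σ, α at .5, .05,
.95) plus seeded random perturbations (default 5 starts in total). α is
optimized on its natural `[0,1]` bound and σ on the log scale. Fitting is
deterministic given the data and the control seed. Non-convergence on all
starts yields a flagged result, not an error.

Out-of-sample comparison (`compare_models()`) refits with α clamped at 0
(pure rule) or 1 (pure similarity) and sums held-out log-likelihood and
RMSE over folds. Classification uses the threshold rule: α < .5 rule user,
α > .5 similarity user; exactly .5 is reported `unclassified` rather than
silently binned. A single-cue strategy is flagged when α > .9 and the
smaller attention weight falls below .05; participants whose fitted betas
are *both* negative (an inverted cue-criterion pattern incompatible with
the monotone environments) are flagged for exclusion.

## Parameter recovery

`run_recovery()` draws true parameters (α uniform on `[0,1]`, betas
jittered around the exemplar-OLS solution, σ at configurable levels),
simulates full test phases, refits with the same cross-validated machinery,
and summarizes recovery of α by Spearman rank correlation, bias, and RMSE
per noise level. At σ = 2 and 128 trials the rank correlation across 30
simulated participants is about .89 (seed 1); recovery degrades as σ grows,
and estimates at a mid-range true α are unbiased to within .1.

One numerical subtlety is worth stating. Simulated responses are by default
rounded to the integers a participant could actually enter. In the
noiseless limit (σ → 0) that rounding leaves a *deterministic* residual
pattern across the 16 stimuli which the mixture can partially absorb — the
global maximum-likelihood solution for a near-pure-rule participant can sit
at α ≈ .3 even though the generating α is .04, and this is a property of
the likelihood surface, not an optimizer failure. Estimator checks in the
noiseless limit therefore use `round_responses = FALSE`; at realistic noise
levels (σ ≥ ~0.5) the rounding contribution is negligible.

## Gaze analysis

AOI geometry follows the experiment: a 1920×1080 screen, exemplar centers
offset ±415 px horizontally and ±235 px vertically from the center (477 px
eccentricity), stimulus footprint 320×180 px enlarged by a 0.1 margin per
side to a 384×216 px AOI, plus an identical center AOI. The constructor
rejects overlapping AOIs, so fixation-to-AOI assignment is unique;
coordinates outside every AOI are labelled `outside` and retained.
Fixations shorter than 80 ms are dropped, mirroring the event detector's
minimum fixation duration; the package deliberately does **not** implement
velocity-based event detection from raw samples — its input is an
event-detector export (participant, trial, onset, duration, x, y).

Metrics:

* **Looking-at-nothing duration** = exemplar-AOI gaze / (exemplar + center
  AOI gaze) per trial; undefined (NA, excluded and counted) when neither
  was fixated.
* **Looking-at-nothing strength** = gaze to the most-similar exemplar's
  AOI / all exemplar-AOI gaze; undefined without exemplar gaze. The most
  similar exemplar minimizes the attention-weighted city-block distance
  under the participant's normalized median cue weights. Ties are broken
  deterministically: smaller unweighted city-block distance first, then
  lexicographically smaller `(x1, x2)`.
* **Time bins.** The post-removal interval is cut into five equal bins;
  fixations straddling a boundary are split pro rata (conserving total
  duration to numerical precision), with an assign-to-onset-bin alternative
  behind a flag. Bins with no exemplar or center gaze contribute 0 rather
  than NA, so per-bin curves average over all trials.
* **Trial-level statistics**: proportion of trials with any exemplar gaze,
  the distribution of distinct exemplar AOIs per trial, whether single-AOI
  trials target the most similar exemplar, and the dominant AOI's share in
  multi-AOI trials.
* **Split-half reliability**: per stimulus, mean looking-at-nothing over
  odd- versus even-numbered presentations, correlated across stimuli
  (Pearson); stimuli with fewer than two presentations are dropped with a
  warning.

## The synthetic cohort generator

The generator exists so the entire pipeline can run and be stress-tested
without any real dataset; its defaults define the package's reference
conditions. Per participant: α uniform on `[0,1]`; betas = exemplar-OLS
`(−9.25, 5.25, 3.25)` plus `N(0, 0.5)` jitter; σ = 2 (roughly the residual
scale a 1–30 response range implies); 8 test blocks (128 trials). Responses
are Gaussian around the mixture prediction, rounded and clipped to 1–30.

The gaze model is a minimal two-process mixture, chosen because no
generative gaze model exists to copy: every trial starts with a center
fixation (15–35% of trial length — the participant still looks where the
test stimulus just disappeared), then with probability
`p = base + slope·α` (defaults .1 + .6·α) one exemplar-location fixation
(lognormal, median 250 ms) lands in the fourth fifth of the trial — where
looking-at-nothing empirically peaks — targeting the most similar exemplar
with probability `bias = .75`, optionally followed by a second exemplar
fixation (probability .25), and a short return to center before the
response click. Trial lengths are lognormal with median ≈ 3.8 s. All
constants live in `cohort_spec()` and are synthetic by construction.

Under these defaults the cohort shows exemplar gaze in ~40% of trials,
single-AOI dominance, a bin-4 peak, and a Kendall τ ≈ .56 between the
*fitted* α and mean looking-at-nothing duration (seed 1, n = 48) — the
synthetic analogue of the association the pipeline is designed to measure.
What passing these checks does **not** show: real gaze data have saccade
dynamics, drift, off-AOI scatter, re-fixations and learning effects the
generator omits, and the real α–gaze coupling strength is an empirical
quantity, not the generator's `slope`. Note also that the generator couples
α to gaze only through the *probability* of exemplar fixations, so
looking-at-nothing *strength* is uncorrelated with α in synthetic data by
construction.

## Statistical layer

Correlations use tie-corrected Kendall τ-b with asymptotic p values
(normality is violated for α and the gaze proportions — Shapiro–Wilk
screens are part of the report); group comparisons use the tie-corrected
asymptotic Wilcoxon–Mann–Whitney test without continuity correction;
trial-level proportions pool trials across participants into a 2×2
chi-square without continuity correction (df = 1). The sensitivity power
analysis for a bivariate correlation uses the Fisher-z approximation
`ρ = tanh((z_{1−α/2} + z_{power}) / √(n−3))` — .49 at n = 48, two-sided
α = .05, power = .95 — and inverts for the required n. The subgroup window
`.1 < α < .9` for the weak-reliance correlation is a configurable default;
the cutoffs are admittedly arbitrary. Exemplar accuracy is the mean of
criterion accuracy (exact match of the response with the exemplar's true
criterion in the test phase) and, when supplied, a location-test accuracy;
exact match is used because a tolerance is not part of the measure's
definition.

## Problem sizes and runtime

The test suite and the acceptance script use the package's reference sizes:
recovery with 30 simulated participants × 128 trials at σ = 2, and a
48-participant synthetic cohort, both cross-validated with 5 optimizer
starts per fold. Unit tests use smaller versions (4 test blocks, 8–10
participants) where the property under test does not depend on the full
design. A cross-validated fit takes well under a second per participant, so
the full pipeline completes in a couple of minutes on one CPU.

## Known limitations

* No hierarchical or Bayesian estimation; per-participant ML only, with
  the known frequentist pull of α toward the rule process under high noise
  (accepted, since rank-order associations are unaffected by monotone
  distortion).
* The generator does not emulate training-phase learning, additive-environment
  cohorts, or response-time structure beyond trial-length scale realism.
* `h` fixed by convention; alternative similarity kernels are out of scope.
* No raw-sample event detection, saccade metrics, or pupillometry.
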