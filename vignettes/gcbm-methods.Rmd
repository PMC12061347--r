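---
title: "Models and design choices in gcbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in gcbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcbm)
```

# The task

Emotion-recognition CBM training presents faces from an ordered morph
continuum of `n_levels` steps (default 15), index 1 being the
unambiguously happy end. A session has four blocks: a 45-trial baseline
(each stimulus three times, uniformly shuffled), two 31-trial training
blocks, and a 45-trial test identical in design to the baseline. The
training blocks oversample the ambiguous middle of the continuum
(endpoints once, stimuli 3–5 and 11–13 twice, 6–10 three times), because
that is where balance points concentrate and where feedback can bite.
Trial timing (600 ms fixation, 200 ms stimulus; 150 ms in the legacy
text-feedback task) is carried in the configuration as metadata only —
the simulator does not model reaction time or stimulus perception
duration.

## Balance points and targets

The balance point of a block is `(n_happy / n_trials) * n_levels`; it is
a function of response counts only. For feedback targeting it is rounded
to the nearest whole number; we round half-up, since the convention for
`.5` ties is not fixed by the estimator itself, and half-up keeps the
worked default (30/45 → 10) and all integer cases untouched. The
training target is the rounded baseline plus a configurable shift
(default +2), clamped to `[0, n_levels]` — baselines near the ceiling
would otherwise produce impossible targets. Control conditions use the
unmodified baseline as the target, so a participant who keeps responding
as at baseline is mostly told "correct" and no criterion shift is
expected. The target is computed once from baseline and held fixed for
both training blocks (re-deriving it per block is possible in principle
but would make the feedback non-stationary; the fixed-target reading is
the natural one for a two-block, single-baseline design).

A stimulus counts as "happy" iff its index is at or below the target.
The boundary is inclusive: with that convention a responder who answers
exactly according to the labels has an expected balance point equal to
the target, which is the property the whole feedback scheme is built
around (and which the tests verify).

## Feedback policies

Text feedback (CBM family) states correctness and the target-implied
emotion: "Correct! That face was happy". Points (gamified family) are
awarded only for correct answers: `max_points` (default 10) minus
`decay_per_step` (default 1) per continuum step between the stimulus and
the participant's own baseline balance point, floored at
`min_points_correct` (default 1). The published description of the
scoring system fixes its qualitative shape — more points nearer the
balance point, zero for errors — but not the exact schedule, so the
linear-decay-with-floor form is this package's parameterisation; every
constant is exposed in `scoring_params()` and the zero-for-errors rule
is hard-coded. Control arms keep their family's feedback modality with
the unshifted target.

# The agent model

Simulated participants carry a latent criterion $c$ on the continuum and
answer "happy" with probability

$$P(\text{happy} \mid i) = \mathrm{logistic}\!\left(\frac{c + 0.5 - i}{s}\right),$$

the simplest psychometric response rule whose expected raw balance point
has a closed form, $\sum_{i=1}^{n} P(\text{happy}\mid i)$
(`expected_balance_point()`). The half-step offset makes an integer
criterion equal its noiseless balance point exactly, which gives the
tests sharp fixed points. Learning is a fixed-step stochastic
approximation: every corrective event (negative text feedback, or a
zero-point trial in the gamified family) moves the criterion by
`learning_rate_eta` toward the response the feedback implied; correct
answers carry no corrective content and leave the criterion unchanged.
The criterion is clamped to `[0, n_levels]`. This rule converges to the
target in expectation and cannot distinguish reward-magnitude effects —
whether the gamified variant's larger empirical shift comes from
proximity-weighted rewards or from framing is outside what this model
can express, and it does not try.

## Seeding

Each session has one root seed. Block schedules and agent response noise
draw from separate child streams derived from it, so the stimulus order
a participant sees is reproducible regardless of how that participant
behaves. The cohort generator similarly derives per-participant session
seeds and a separate stream for demographics and mood noise from its
root seed; a cohort is byte-identical across runs with the same seed.

# The synthetic cohort

`simulate_cohort()` emulates a three-arm single-session randomized
trial. Defaults are the post-exclusion arm sizes of a large online
trial of this design (400 text-feedback training, 397 gamified training,
119 control), ages uniform on 18–30, and a 55.1/42.8/2.1% gender mix.
Initial criteria are drawn per participant from N(7.5, 1.2) — balance
points concentrated in the ambiguous 6–10 band — with response-noise
scale 0.75. Learning rates were calibrated once, by simulating sessions
over a grid, so that mean raw balance-point shifts under the default
design are ≈ +0.9 (text feedback, η = 0.10) and ≈ +1.35 (gamified,
η = 0.19), the shift magnitudes reported for this intervention family;
control arms use their family's learning rate and show shifts ≈ 0.
These are calibration inputs of the generator, not quantities the
package claims to predict.

Mood totals model a 22-item scale summed over 7-point items, range
22–154. The published account of the scale describes 5-point items
(range 22–110), but the reported arm means (≈ 96–105) and SDs (≈ 25–28)
are incompatible with a 110 ceiling, while the original instrument uses
7-point items; we therefore default `score_range` to (22, 154) and leave
it configurable. Post-training totals are

`post = pre + delta[arm] + beta * (bp_shift − E[bp_shift | arm]) + N(0, noise_sd)`

truncated (clamped) to the score range. The arm effects default to
δ = 5.35 / 7.01 / 3.63 mood points (text training / gamified training /
control). Centring the balance-point coupling on the arm's expected
shift keeps each δ equal to the arm's mean improvement whatever the
coupling `beta` (default 1 mood point per continuum step, a deliberately
modest value — the data needed to estimate it do not exist at desk
scale). `noise_sd` defaults to 13: with the default arm effects and
sizes this change-score dispersion reproduces a group × time interaction
F of about 4.4 on mood, the magnitude reported for cohorts of this size.
Truncation pulls extreme means slightly toward the centre (≈ 0.3 points
at the gamified arm's post mean); tests that check mean recovery allow
for this.

What the generator does *not* emulate: reaction times, fatigue,
attention-check failure, dropout, item-level mood responses, or any
dependence of learning on reward magnitude. Passing tests therefore
demonstrate internal consistency of the engine and pipeline, not
properties of human data.

# The analysis pipeline

`run_full_analysis()` fixes the order: outlier filtering → descriptives
→ mixed ANOVAs → pairwise contrasts.

* **Outliers** are removed by Tukey fences (1.5 × IQR beyond the
  quartiles), quartiles by linear interpolation between order statistics
  (`quantile type 7`, the common spreadsheet/statistics default); values
  exactly on a fence are kept. The variable the published analysis
  filtered on is not stated, so the pipeline applies the rule within arm
  to post-training values of the primary outcomes (both, by default;
  configurable) and reports a per-arm audit. The filter runs exactly
  once — it is not re-applied to the kept set, where recomputed fences
  could remove further points.
* The **mixed ANOVA** is the standard split-plot with arm as the
  between-subject factor and pre/post as a two-level within factor,
  fitted via `aov` with an `Error(participant)` stratum. With two time
  points the interaction F is identical to a one-way ANOVA on change
  scores; the test suite uses an explicit sums-of-squares change-score
  oracle to verify this equality. Partial η² is
  SS(interaction) / (SS(interaction) + SS(within-error)). With three
  arms and N participants the interaction df are (2, N − 3).
* **Contrasts** are OLS regressions of the post score on an arm
  indicator, optionally adjusting for the baseline score, age, and
  gender (treatment-coded, largest category as reference; undisclosed
  gender kept as its own category). CIs use the t distribution on
  residual df; no small-sample corrections and no multiple-testing
  adjustment across the three arm pairs, matching how such trials report
  unadjusted pairwise p-values. Collinear designs raise an error naming
  the aliased terms rather than silently dropping them.
* The **power solver** iterates n upward under the exact noncentral-t
  power of the two-sided two-sample t test (noncentrality
  $d\sqrt{n/2}$ on $2n-2$ df). The exact form matters: at d = 0.2,
  80% power, α = .05 it returns 394 per group where the normal
  approximation gives 393.

## Numerical notes and degenerate inputs

Balance points from empty blocks, fewer than four values in the outlier
filter, arms with fewer than two participants, unknown conditions, and
frequency maps that do not cover the continuum all raise early, labelled
errors. A continuum needs at least three levels — a one-stimulus "task"
is rejected as configuration error rather than given a degenerate
schedule. When every participant has an identical change score the
interaction F is an indeterminate 0/0; the equal-means-with-residual
case returns exactly 0.

## Problem sizes used in the tests

The stochastic suite uses 200 sessions for the control-null check, 120
sessions per learning-rate level for monotonicity, 600 replicates at
n = 30/arm for type-I calibration, 300 replicates at n = 394/arm for
the empirical-power check, and 100 replicate cohorts of 160 participants
for arm-effect recovery — sizes chosen so each Monte-Carlo interval is
tight enough to be informative while the whole suite runs in a couple of
minutes on one core.
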