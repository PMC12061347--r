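# gcbm

Task engine, simulated participants and trial analysis for **cognitive
bias modification (CBM)** training of emotion recognition, including the
**gamified variant (GCBM)** that replaces corrective text feedback with
graded point rewards.

## The problem

People with a negative interpretation bias tend to classify ambiguous
facial expressions as sad. CBM training works on a morph continuum of 15
face stimuli interpolated from unambiguously happy (index 1) to
unambiguously sad (index 15). A participant's **balance point** — the
continuum position where they are equally likely to answer "happy" or
"sad" — is estimated from a block of trials as

```
balance point = (n_happy / n_trials) × n_levels
```

so 30 "happy" answers in a 45-trial block give (30/45) × 15 = 10.
Training then delivers feedback keyed to a **target balance point** equal
to the rounded baseline plus a shift of +2 (training arms) or the
unchanged baseline (control arms): faces at or below the target count as
"happy". Text feedback says "Correct!/Incorrect! That face was …"; the
gamified variant instead awards points for correct answers only, graded
by proximity to the participant's own balance point, and nothing for
errors. A session is four blocks: 45-trial baseline, two 31-trial
training blocks (ambiguous middle stimuli shown most often), 45-trial
test.

The package provides this engine end to end, a psychometric agent model
(logistic decision criterion `P(happy|i) = logistic((c + 0.5 − i)/s)`
with a fixed-step learning rule driven by corrective feedback), a
synthetic cohort generator with mood outcomes, and the randomized-trial
analysis pipeline: Tukey-fence (1.5 × IQR) outlier removal, group × time
mixed ANOVA with partial η², baseline-adjusted pairwise regressions, and
a-priori sample-size computation via the exact noncentral-t distribution.

## Worked example

```r
library(gcbm)

# balance point and training target
bp <- estimate_balance_point(rep(c("happy", "sad"), c(30, 15)), 15, "baseline")
bp$raw                                             # 10
compute_target_balance_point(bp, "gcbm_training")  # 12

# a-priori sample size: d = 0.2, 80% power, two-sided alpha = .05
power_n_per_group(0.2, 0.80, 0.05)$n_total         # 788 (394 per group)

# simulate a small three-arm trial and analyse it
coh <- simulate_cohort(c(cbm_training = 60, gcbm_training = 60, cbm_control = 40),
                       root_seed = 11)
report <- run_full_analysis(coh$outcomes)
report$descriptives$bp[, c("condition", "improvement")]
#       condition improvement
# 1   cbm_control -0.03333333
# 2  cbm_training  0.81871345
# 3 gcbm_training  1.35028249
```

The improvements are the mean post-minus-pre balance-point shifts per
arm: training arms move upward (more faces called happy) by roughly one
continuum step, the control arm does not. `report$anova` holds the
group × time interaction tests and `report$contrasts` the adjusted and
unadjusted pairwise treatment effects.

A command-line front end is installed with the package
(`exec/gcbm`): subcommands `schedule`, `simulate`, `analyze`, `power`.

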