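---
title: "Models and methods behind sacclearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sacclearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacclearn)
```

## The task and the generative model

`sacclearn` analyses (and simulates) a saccadic hidden-target task. On a
ring, an unseen target location is the mean direction of a von Mises
distribution; on every trial a visual hint is drawn from that
distribution, and the observer reports a running estimate of the target
with an eye movement — either toward the estimate (pro-saccade) or to the
diametrically opposite point (anti-saccade). A block has 20 trials with
one fixed target; after trial 10 the required response modality flips.
Blocks cross two difficulties (von Mises concentration $\kappa = 30$,
spread $\sigma_{dist} = \sqrt{1/\kappa} \approx 10^\circ$, versus
$\kappa = 5 \approx 26^\circ$) with the two modality orders, in a fully
counterbalanced 40-block design over 20 target locations used twice each.
A separate calibration task (blocks of 10 pro then 10 anti saccades to
visible targets) measures each observer's modality-specific motor noise.

Because observers' responses are tightly localised around the target,
all analysis runs on *signed angular errors* in degrees, wrapped to
$(-180, 180]$, rather than on circular statistics. This mirrors the
small-angle regime of the task and keeps every downstream model linear.

## Synthetic agents

The simulator's agent produces its trial-$t$ guess error $g_t$ from the
hint errors $h_t$ and its own history:

$$ g_t = b_0 + \sum_{j=1}^{3} w^{(g)}_j\, g_{t-j}
       + \sum_{j=0}^{3} w^{(h)}_j\, h_{t-j}
       + w_{ch}\, \bar h_{1..t} + w_{cg}\, \bar g_{1..t-1}
       + \varepsilon_t, \qquad
   \varepsilon_t \sim \mathcal{N}(0, \sigma^2_{motor}) $$

with $\sigma_{motor}$ specific to the modality executed on trial $t$.
This single recurrence spans the entire candidate-model space used for
fitting (current/lagged hints, lagged guesses, and the two cumulative
averages), so data can be generated from any candidate model's dynamics
and fed back into the fitting machinery for parameter and model
recovery. Design choices worth stating explicitly:

* **Early trials.** The first trials of a block lack lagged
  predecessors. Missing lag terms are dropped and their weight mass is
  added to the current-hint weight, so an agent whose weights sum to one
  follows the hint (plus motor noise) on trial 1 — the only sensible
  naive behaviour. Model fits use trials 4–10 (or 2–10 for
  single-predictor models), so this convention only seeds the
  recurrence and never enters a fitted likelihood.
* **Reset at the switch.** With `reset_on_switch = TRUE` the modality
  switch acts as a full memory boundary: lagged guesses, lagged hints
  and both cumulative averages restart, making trial 11 statistically
  identical to trial 1. This is deliberately the *strong* no-transfer
  hypothesis; a weaker reset (only lagged-guess terms zeroed) would
  leave residual transfer through remembered hints, which the
  time-resolved regressions would pick up.
* **Motor noise is Gaussian on angle.** Only its calibration-task
  magnitude is empirically constrained; Gaussian is the natural choice
  in the small-angle regime and makes the half-normal identity
  $E|\varepsilon| = \sigma\sqrt{2/\pi}$ available for converting
  between SDs and mean absolute errors.
* **Confidence.** The rating is `round(offset - scale * s_t)` clipped to
  1..6, where $s_t$ is the agent's internal uncertainty
  ($\sqrt{\sigma_{dist}^2/t^{*} + \sigma_{motor}^2}$ with $t^*$ the
  count of trials since the last memory boundary). A small jitter
  (`confidence_noise_sd`, default 3°) perturbs $s_t$ before the mapping:
  a perfectly deterministic rating would be constant across blocks of
  the same condition and degenerate every paired test on confidence,
  which no real rating scale does.
* **Failures.** Timeouts/tracking losses (probability `p_timeout`) are
  flagged at source with missing endpoints; wrong-modality executions
  (probability `p_wrong_type`) rotate the endpoint by 180° and are *not*
  labelled — they must be caught downstream by the error threshold,
  exactly as in real data.

Defaults follow the study conditions: 20 participants, 40 blocks,
$\kappa$ of 30/5/80 (easy/hard/training), 4 calibration blocks, motor
noise SDs of 6.3° (pro) and 9.5° (anti) matching the calibration-task
error distributions, and a reference strategy that weights the running
mean of previous guesses at 0.7 and the current hint at 0.3 — the
strategy class the regression analysis identifies.

## Preprocessing

Errors are signed differences estimate − target; anti-saccade endpoints
are reflected by 180° first. Trials with an absolute error strictly
greater than 100° are flagged as wrong-response-type failures: executing
the wrong modality lands the inferred estimate near 180°, far above the
threshold that separates the two modes of the empirical error
distribution. The threshold is applied after the anti reflection — that
is where wrong-modality trials appear near 180° — and the comparison is
strict at exactly 100°. Failed rows are flagged, never deleted, so
exclusion accounting stays reproducible from the table itself.

## Learning metrics and the performance bound

Learning curves average within subject first and report the across-
subject mean and SEM ($N$ = subjects). The first/second-half contrast
(trials 1–5 vs 6–10), the guess-versus-hint contrast, and the modality
difference index $(\text{pro} - \text{anti})/(\text{pro} +
\text{anti})$ of mean absolute errors are all paired, two-sided tests
across subjects.

The best achievable mean absolute error combines two independent error
sources in quadrature:

$$ \gamma(t) = \sqrt{\gamma_{Motor}^2 + \gamma_{Hint}(t)^2 }, \qquad
   \gamma_{Hint}(t) = \sqrt{\tfrac{2}{\pi}}\,
   \frac{\sigma_{dist}}{\sqrt{t}} $$

where $\gamma_{Motor}$ is the calibration-task mean absolute error and
$\sigma_{dist} = \sqrt{1/\kappa}$ converted to degrees. Two readings of
this bound — quadrature of mean absolute errors, or addition of
variances followed by the half-normal conversion — coincide under
normality because both mean absolute errors share the $\sqrt{2/\pi}$
factor; the package tests this identity to machine precision.

Two numerical caveats are documented by tests rather than hidden:
$\sqrt{1/\kappa}$ is a concentrated-regime approximation, about 1% below
the exact von Mises dispersion at $\kappa = 30$ but about 7% below it at
$\kappa = 5$. The Monte Carlo optimality check (a cumulative-mean
observer over 2000 blocks) is therefore asserted against the analytic
bound in the easy condition, where the approximation is accurate, and
against an exact-dispersion oracle (numerical integration of the von
Mises density) in the hard condition. The curve-level comparison uses
the mean standardised deviation across trials 1–10 within $\pm 2$: a
strict per-trial $2\sigma$ band would flag pure Monte Carlo noise in a
quarter of runs, while the curve-level statistic still detects genuine
bound violations (the hard-condition approximation bias, for instance,
shifts it beyond +2.5).

## Model comparison

Predictors are built per block on the signed-error scale: current and
lagged hints ($t \ldots t-3$), lagged guesses ($t-1 \ldots t-3$), the
cumulative hint mean *including* the current hint, and the cumulative
guess mean *excluding* the current guess (the running average of all
previous guesses — the textual reading of the cumulative-guess
strategy). Lags never cross block boundaries; failed trials are skipped,
so a lag refers to the previous valid trial; cumulative averages use
valid trials only.

Eleven candidate models (five single-predictor strategies, the
two-cumulative-average combination, and lag models up to three steps)
are fitted per subject by OLS on the common complete-case rows of
trials 4–10 (2–10 for the single-predictor set), so every model sees
identical data. Comparison uses the Gaussian-likelihood BIC
$n\ln(RSS/n) + k\ln n$ — $k$ counts coefficients plus the error
variance, a convention that cancels in BIC differences — rescaled to
$\Delta_i = BIC_i - \min_j BIC_j$ and converted to Bayesian weights
$\omega_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$, the probability
of being the best model among those tested. Group results average
weights across subjects; per-subject fits pool conditions unless a
split by modality or difficulty is requested. Zero-variance predictors
abort the fit with a singularity error rather than being silently
dropped into an unidentifiable design.

The forward stepwise analysis treats blocks as observations: the
trial-10 guess error is predicted from that block's guess errors 1–9
and hint errors 1–10, predictors are added greedily while the 10-fold
cross-validated RMSE improves, and an intercept-only null RMSE is
reported as the baseline. Folds are assigned over blocks,
deterministically from the seed. The time-resolved regressions fit, at
every trial index, the current guess error on the guess error 1–3
trials back plus the current hint error, across a subject's blocks
(strict trial-index lags here, since the question is specifically
whether trial 10 informs trial 11), with across-subject one-sample
t tests on the weights.

## Transfer analysis

To compare performance across the modality switch, per-subject
per-trial-index mean absolute errors are corrected by subtracting the
subject's calibration motor error for the modality used at that trial.
The correction is applied to per-subject means, not single trials — the
mean-level subtraction is what the quantity of interest (a difference
of condition means) requires, and it is far more stable. Corrected
values may be negative and are not clipped; within-modality contrasts
are invariant to the correction, which a test asserts. Contrasts of
trials 10 vs 11 (transfer probe) and 1 vs 11 (naive baseline) are
paired two-sided t tests per condition, reported without
multiple-comparison correction (none is applied, and the output labels
this).

The three-way repeated-measures ANOVA (difficulty × trial ×
order-or-modality, all within subject) tests each effect against its
own subject-by-effect error stratum. With two-level factors, sphericity
corrections are vacuous (every effect has one numerator degree of
freedom), so none is applied. The implementation's contract is
behavioural: on null simulations the type-I error rate of every effect
sits at the nominal 5%, and on small instances the parametric p agrees
with a within-subject permutation oracle — both are asserted in the
test suite. Fully degenerate input (no variation at all) reports
$F = 0$, $p = 1$ rather than 0/0.

## What the simulations do and do not show

The generator emulates the statistical skeleton the analysis assumes:
von Mises hints, linear integration with modality-specific Gaussian
motor noise, discrete confidence, counterbalanced designs, and the two
failure routes. It does not emulate gaze kinematics, reaction times,
attention lapses beyond uniform failure probabilities, heavy-tailed
motor error, or any drift of strategy within a session. Green tests
therefore certify that the *pipeline* recovers known generative
structure at study scale — not that real observers satisfy the
generator's assumptions.

Problem sizes were chosen to make the checks decisive at interactive
cost: recovery studies run 50 cohorts of 20 subjects × 40 blocks per
generating model; the bound check uses 2000 blocks per condition; null
calibration uses 1000 replicates. All stochastic steps take explicit
seeds, and a full pipeline run is reproducible from its JSON config and
seed alone.
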