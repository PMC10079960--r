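---
title: "Choice models and neural encoding for serial-reversal bandit tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choice models and neural encoding for serial-reversal bandit tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `revbandit`, the
assumptions behind them, the parameter choices that matter, what the
synthetic-data generators do and do not emulate, and the numerical decisions
a maintainer should know about.

## The task and its simulator

The task is a two-alternative forced choice with probabilistic outcomes and
serial reversals. A correct choice (the currently rewarded port) is rewarded
with probability `p_outcome = 0.85` (12 uL per reward); an incorrect choice
triggers a punishment tone with the same probability; the remaining 15% of
trials deliver no outcome either way. Reward history is monitored in a
10-trial moving window and the rewarded side switches when 8 of the last 10
completed choices were to the rewarded port.

Two aspects of the rule are under-determined by that description and were
fixed as follows:

- **The window resets at each switch.** If it did not, the first trials of a
  new block would count the old block's "correct" labels against the new
  contingency. With the reset, 8 consecutive correct choices from block
  start trigger the next switch — so a perfectly accurate agent completes
  exactly 8 trials per block, which is the structural constant the
  acceptance script verifies.
- **Omissions never enter the window**, nor any stay or likelihood
  computation: a trial without a registered choice carries no evidence
  about side preference. Omissions are generated with a configurable
  probability (`p_omission`, default 0).

Trial timestamps are a fixture choice, not science: inter-event latencies
are log-normal around the protocol's fixed delays (`hold` 0.5 s, outcome
delay 0.5 s, ITI 3 s) with median initiation and choice latencies of 0.3 s
and 0.5 s. Every session draws from one seeded generator and identical
`(policy, params, config, seed)` reproduce a byte-identical session.

One empirical subtlety the test suite documents: the raw correct-choice
fraction of a Q-learning agent is *not* monotone in the inverse temperature
`beta` once reversals are active. Stronger exploitation reaches the 8-of-10
criterion sooner, producing more reversals and more immediate post-reversal
errors; at `beta = 10` the fraction is slightly below `beta = 3`. The
monotonicity property is therefore asserted under a fixed contingency, where
it holds strictly.

## Choice models

All models operate on the coded series of completed trials: `c = +1/-1` for
right/left, `R = 1` for reward, `r = c * R`.

| model    | parameters (bounds)                                            | k  |
|----------|----------------------------------------------------------------|----|
| wsls     | lapse `epsilon` [0, 1]                                         | 1  |
| qlearn   | `alpha` [0, 1], `beta` [0, 50]                                 | 2  |
| qforget  | `alpha`, `beta`, forgetting `phi` [0, 1]                       | 3  |
| rlogreg  | stickiness, reward sensitivity, bias [-10, 10], `tau` (0.01, 50] | 4 |
| logreg   | intercept + 5 choice lags + 5 reward lags                      | 11 |

The bounds are a stability choice (none are stated by the protocol): `beta`
above 50 is observationally indistinguishable from a step function, `tau`
below 0.01 trials decays within machine precision of one step. The
nonlinear models are fitted by L-BFGS-B from 20 uniform-random seeded
starts; the best negative log-likelihood wins, ties broken by first index,
and an optimum on a bound is flagged (`boundary = TRUE`) rather than
silently accepted — near-deterministic data legitimately push `beta` to its
cap. The 5-lag logistic regression is an ordinary GLM and is fitted with
`glm.fit`.

Conventions for trials lacking history: the recursive state starts at
`rho(0) = 0` with no stickiness term on trial 1 (`c(0) = 0`); the
win-stay/lose-shift rule assigns probability 0.5 to the first trial; the
5-lag regression drops trials 1–5 from its likelihood. AIC is `2k + 2 nll`,
BIC uses the number of likelihood trials. Probabilities are clamped to
`[1e-12, 1 - 1e-12]` before logs.

The lapse semantics of win-stay/lose-shift: with probability `epsilon` the
choice is uniform random, otherwise the rule applies, so
`P(stay | win) = (1 - epsilon) + epsilon / 2`.

## Behavioral metrics

Win-stay / lose-stay probabilities condition on the previous *completed*
trial; "lose" means any unrewarded completed trial (punished or
no-outcome) — the natural reading when 15% of trials have no outcome, and a
choice the tests treat consistently. Relative reward stay is the log odds
ratio of win-stay against lose-stay; degenerate cells receive the
Haldane–Anscombe 0.5-count correction and the result is flagged. The
optogenetic contrasts `DeltaWinStay`/`DeltaLoseStay` condition on the
*prior* trial's light status and pool transition counts across sessions
(never across session boundaries). Local reward rate is
`rewards x volume / elapsed time` over the prior 5 trials, elapsed time
measured trial-start to trial-start, in uL/min.

## The synthetic neural generator

`sample_ground_truth()` draws, per neuron: an intercept (baseline dF/F),
one temporal kernel per tuned event predictor, scalar gains for tuned
continuous predictors, and a noise SD. Kernel shapes are raised cosines —
"brief" (~1 s transient), "persistent" (support beyond 5 s, emulating the
slow increase after reward omission), "biphasic" — *projected onto the
predictor's own B-spline basis*. That projection is deliberate: it makes
every ground truth exactly representable by the encoding model, so the
round-trip identity (design matrix times true coefficients equals the
noiseless trace to machine precision) is a meaningful structural test of
the whole pipeline rather than an approximation.

Traces are synthesized at 20 Hz, the rate consistent with 200-ms
cross-validation chunks spanning about 4 imaging frames. Noise is white
Gaussian, matching the model's assumption; an AR(1) switch exists for
robustness experiments only. Head velocity is a smoothed positive series
with Gaussian bursts at initiation and choice pokes.

What passing tests therefore show: that the estimator recovers effects that
have the generative structure the model assumes. They do not show
robustness to model mismatch — real calcium traces have asymmetric
indicator kinetics, autocorrelated and signal-dependent noise, slow
baseline drift and segmentation cross-talk, none of which the generator
emulates.

## The encoding model

Event kernels use clamped uniform-knot cubic B-spline bases (partition of
unity on the window): cue/initiation/choice get 7 bases on [-1, +2] s;
outcome-tethered predictors (O+, O-, choice-side interactions ChxO+/-, and
RPE+/- kernels scaled by the trial's prediction-error magnitude) get 10
bases on [-0.5, +6] s, wide enough for the persistent post-omission
signals. These windows are configurable defaults, not protocol constants.
`dQ` and `sQ` are piecewise constant, stepping to their post-update values
at each outcome; reward rate steps at trial start; head velocity is
linearly interpolated to the frame grid. Interaction events are coded
contralateral to a session-level recording-hemisphere field.

Fitting is elastic net with mixing 0.95 (near-lasso), intercept
unpenalized. Continuous columns are z-scored before fitting and the
coefficients mapped back; spline columns are already bounded in [0, 1] and
enter as-is. The lambda path is an explicit log-spaced sequence of 60
values down to `1e-6` of the data-derived maximum: supplying the sequence
explicitly keeps every cross-validation fold on the same grid (auto paths
truncate per fold, which misaligns the fold-FVE matrix and inflates the
1-SE threshold), and the deep lower end lets near-noiseless traces reach an
essentially unpenalized solution.

Cross-validation uses 50 folds assigned at the granularity of 200-ms
chunks, each trial's chunks dealt across folds in a rotating order, so no
chunk is split across folds and every trial is represented roughly equally
in each fold. Lambda is the largest value whose mean fold FVE is within one
standard deviation (across folds, at the FVE-maximising lambda) of the
maximum — ties on the path resolve toward larger lambda (the sparser
model) by construction. The *reported* FVE is computed from the pooled
held-out predictions at the selected lambda; a training-FVE switch exists
but cross-validated FVE is the honest default, and the 5% task-tuned
threshold is applied to it.

Tuning indices refit the reduced model from scratch on the same folds, with
its own lambda selection — reusing the full model's lambda would handicap
the reduced model and inflate indices. One identifiability caveat matters:
because the outcome follows the choice by a fixed 0.5 s delay, a single
outcome kernel (say O+) is exactly spanned by the choice kernel plus the
complementary outcome kernel (O-), so the tuning index of one outcome
predictor alone is structurally near zero. The identifiable quantity is the
grouped index — dropping the outcome group together with the RPE kernels —
and that is what the tests assert for injected effects.

Degenerate inputs: an all-constant trace yields an intercept-only fit with
a warning; a design with every predictor dropped is fit as intercept-only
(the lambda-to-infinity limit); rank deficiency is handled by the penalty
itself.

## Pathway statistics

The pathway kernel is the per-lag RMS of single-neuron kernels; it captures
modulation magnitude, never direction, and is non-negative by construction.
Confidence bands resample neurons with replacement — the same resample
across lags, so the band is a band over curves — with BCa correction, the
acceleration estimated by jackknife over neurons. When the correction is
undefined (degenerate resamples, extreme bias term) the interval falls back
to percentile and says so. The pathway difference test builds a BCa
interval for `rms_A - rms_B` per lag (resampling within each pathway,
jackknife over the pooled set); a lag is significant when the 95% interval
excludes zero. Per-lag tests are not corrected for multiple comparisons
across lags. Default 10,000 bootstrap samples; the null-calibration test
uses 1,000 samples, 200 replicates and 40 task-relevant neurons per
pathway — real pathway populations are larger still, and the BCa interval's
small-sample over-rejection (measured near 9% at 12–15 neurons) subsides
toward nominal as the population grows.

## Problem sizes used by the test suite

Parameter recovery runs 20 agents at 1,000 trials (the study's stated
recovery conditions); model recovery uses 20 sessions of 600 trials;
encoding round trips use 40–50-trial sessions at 20 Hz (roughly 10–15
thousand frames, always at 50 folds); the calibration suite runs 200 null
replicates at 1,000 bootstrap samples. These sizes were chosen so each
property is measured with useful precision while the whole suite stays
comfortably interactive.

## Known limitations

- No hierarchical fitting across animals or sessions; every session and
  neuron is fit independently.
- The Gaussian identity-link model is the only likelihood for traces; no
  spike inference or non-Gaussian noise.
- Generator realism is deliberately limited (see above); conclusions about
  real data require the usual caution.
- The task engine does not emulate hardware state machines, shaping stages
  or video.
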