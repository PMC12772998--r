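---
title: "Models and methods behind metaforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the task, the behavioral model, the synthetic neural generator, the
encoding/decoding analyses, and — importantly — the places where a design
choice was genuinely open and what we chose.

## The task environment

Three radially arranged patches hold two reward ports each. A *trial* runs
from leaving one port to leaving a different one; its *run period* ends at
the nose poke and its *outcome period* (pause) ends at the next movement
onset. Ports carry nominal reward probabilities from {0.2, 0.5, 0.8},
sampled uniformly under two constraints: exactly one patch has the highest
mean, and no patch holds {0.8, 0.8}. The depletion–repletion rule: each
within-patch re-visit to a port multiplies its effective probability by
`discount` (default 0.8), and a patch switch instantaneously restores the
departed patch to nominal. Consecutive visits to the same port are never
rewarded.

Two choices here were open:

* *Instantaneous repletion.* Whether an unvisited patch recovers gradually
  is not specified by the task description; we reset the departed patch's
  counters at the switch event. Only the departed patch needs resetting —
  all other patches are already at zero by the state invariant.
* *Per-port depletion counters.* Depletion advances only for the visited
  port, not its within-patch partner.
* *Session start.* The port where a session begins counts as one
  within-occupancy visit in both the environment and the agent, so an
  immediate alternation back to it is already a depleted re-visit.

Timing is synthetic but consequential for the geometry analyses: run
durations are log-normal (median 3 s on stay trials, 4.5 s on switch
trials, sdlog 0.2) and the pause is 5 s after reward versus 0.8 s after
omission. The 0.8 s omission pause exactly covers the pre-move analysis
window, mirroring the fact that animals pause at ports after both
outcomes.

## The behavioral model

Each port i is tracked by Beta pseudo-counts (α_i, β_i), initialized to 1
at each session start, with value Q_i = α_i/(α_i+β_i). After a reward,
α_i ← α_i + 1. After an omission,

β_i ← β_i + (1 − μ_i)/(1/d_i − μ_i),  μ_i = (α_i + 1)/(α_i + β_i + 2),

where d_i is the agent's depletion estimate for that port: 1 at patch
entry, multiplied by the **depletion factor** at each same-port re-visit,
and reset to 1 (for all ports) when the agent switches patch. The d used by
the omission update is the one already multiplied for the current re-visit.
At d = 1 the update is the textbook +1; as d → 0 the increment vanishes —
an omission at a port believed depleted carries no information about its
underlying rate. Non-chosen ports relax toward 1 each trial:
x ← (x − 1)(1 − decay) + 1.

The current patch's value is γ·Q_upcoming + (1 − γ)·Q_past, where Q_past is
the occupied port's value and Q_upcoming is the partner port's value
multiplied by the depletion estimate that would apply on that prospective
visit (1 if the partner is unvisited this occupancy). Alternative patches
take the plain mean of their two port values. Patch choice is a softmax
over V_stay = β_stay·Q + b_stay for the current patch,
V = β_go·Q (+ b_turn for the patch to the left, cyclically 1→2→3→1) for the
alternatives; port choice on switches is a second softmax with β_port. The
**switch value** is max V_alternative − V_current; with a sizable stay bias
it is typically negative.

### Parameters

| parameter | range | default | role |
|---|---|---|---|
| γ | [0,1] | 0.5 | weight on the upcoming port in the current patch value |
| depletion factor | (0,1] | 0.8 | multiplier of d per re-visit; 1 = depletion-blind |
| decay | [0,1) | 0.05–0.3 | per-trial forgetting toward flat pseudo-counts |
| β_stay, β_go | ≥ 0 | 5 | inverse temperatures, current vs alternative patches |
| β_port | ≥ 0 | 3 | port-stage inverse temperature |
| b_stay | ℝ | 1 | stay bias (cost of leaving) |
| b_turn | ℝ | 0 | bias toward the left neighbor |

Two regimes bracket meta-learning: *early* (depletion factor 1, decay 0.3 —
recency-weighted learning with fast forgetting) and *late* (factor 0.8,
decay 0.05 — the rule incorporated, memory persistent).

### Fitting

The likelihood multiplies the patch-stage probability of every chosen
patch and, on switch trials, the port-stage probability of the chosen
port; beliefs are replayed trial by trial with session resets. Optimization
runs in a transformed space (logit for unit-interval parameters, log for
temperatures, identity for biases) with BFGS from five fixed jittered
starts; the trial loop is compiled (Rcpp), and a pure-R reference
implementation (`value_trace()`) is tested to agree with it to 1e-13.
Convergence: relative objective change 1e-10, optimizer iteration cap 400,
a fit is flagged (not errored) if the gradient norm stays above 1e-2.
The hierarchical fit is an EM: the E step computes per-day MAP estimates
under a diagonal Gaussian prior with Laplace curvatures (numerical
Hessians), the M step sets the prior mean to the MAP average and the prior
variance to the mean of squared deviations plus Laplace posterior
variances, iterating until the prior mean moves less than 1e-3.

## The synthetic neural generator

Each neuron has a baseline log-rate (2–12 Hz), a Gaussian goal-progress
tuning bump with mild per-journey amplitude modulation (so the 48
journey×progression indicators have real structure to absorb), and a
value-gain bump over the 11 progression bins whose sharing defines the
neuron's generality class — one profile for all journeys (progression), per
turn direction (action), per patch, per journey, or none. Spike counts are
Poisson with the bin duration as exposure; rates are capped at 200 Hz.

Three generator decisions deserve emphasis:

* **Which value is encoded when.** Bins 1–4 carry the origin-referenced
  switch value of the trial. Bins 5–8 (after the choice point) carry an
  *arrival-referenced* switch value: the same pre-outcome belief
  re-evaluated from the destination port, with the patch-switch repletion
  applied. On stay trials the two are nearly identical; on switch trials
  the arrival value expresses the anticipatory reset at patch entry —
  without it, no decoded-value repletion can exist in the synthetic data by
  construction. The outcome bins interpolate linearly from the arrival
  value (bin 9) to the next trial's value (bin 11) when the value-transition
  flag is on, linking the terminal value of one trial to the initial value
  of the next. Decoder *targets* remain the origin-referenced per-trial
  value throughout.
* **Goal-progress parameterization.** The run period is normalized time in
  8 equal bins; the outcome period is 3 bins over the pause. On the fine
  grid used for geometry, the outcome-period progression coordinate is
  anchored to time-before-movement-initiation over a fixed 0.8 s span
  (clamped earlier), so the pre-move window samples the same
  task-structure coordinate after long (reward) and short (omission)
  pauses. With naive normalized pause time, the post-reward and
  post-omission windows would encode different progression coordinates and
  the outcome-shift geometry would be dominated by that artifact.
* **Gain scale.** The default gain amplitude (0.5 × U(0.5, 1.5) log-rate
  per unit switch value, random sign) was chosen once so that single-neuron
  value modulation is detectable by the GLM comparison at desk scale —
  consistent with value modulation being prevalent rather than marginal in
  frontal cortex. A consequence is that population decoding on clean
  synthetic data explains more held-out variance than typical in-vivo
  recordings; the generator has no noise correlations, drift, or
  model-mismatch, so decoding here is an upper bound, not a forecast.

What the generator does *not* emulate: correlated noise across neurons,
electrode drift and unit instability, spike sorting artifacts, non-Poisson
dispersion, and any neural computation beyond the fitted behavioral
model's latents. Passing tests therefore demonstrate that the analysis
chain recovers known ground truth, not that real data will behave as
cleanly.

## Encoding analysis

For each neuron, one row per (stay trial, run bin) with a log bin-duration
offset. The reduced model has the 48 journey×progression indicators; the
four value models add switch-value×bin interactions at 8/16/24/48
granularity. All models for a neuron share a single L1 penalty selected by
trial-grouped 5-fold cross-validation *on the reduced design*; selecting
the penalty per model lets the larger value designs choose heavier
shrinkage, which degrades the shared structure terms and can make the true
value model score worse than the reduced one — sharing the penalty keeps
everything but the value block identical across models. Held-out deviance
fractions come from repeated trial-level 10-fold cross-validation
(per-repeat fractions, identical fold draws across models), with the null
being a training-set intercept-plus-offset model. Categorization: a neuron
is value-modulated if any value model beats the reduced model
(one-sided rank-sum over repeat fractions, Holm, p < 0.01); among the four
granularities, a model that significantly beats all others wins, and
statistically indistinguishable leaders resolve to the most parsimonious
(progression < action < patch < journey by parameter count; the
action/patch tie resolves to action by fixed order). Repeat-level (not
fold-level) fractions feed the tests.

## Population geometry

Single-trial rates are estimated by duration-weighted Gaussian-kernel
smoothing (σ = 50 ms) of the fine-grid counts, evaluated on windows
anchored at movement initiation: the navigation window (0 to +3 s) and the
pre-move window (−0.8 to +0.2 s). Deep-learning denoising of single-trial
dynamics is out of scope here; kernel smoothing is adequate for synthetic
data whose latents are known, and is used wherever single-trial states are
needed. Condition averages (grouped by proximity to the next switch,
optionally crossed with action/patch/journey) are stacked into a
(conditions × time) × neurons matrix and decomposed by column-centered PCA
(no per-neuron variance scaling — rates are already on a common scale).
The component pair for the outcome-shift analysis is selected
automatically as the two components among 2–5 whose condition means
correlate most strongly (Spearman) with proximity-group order; in real
data this selection was done per day by inspection, so the automatic rule
is a stand-in and is reported alongside results. The shift-cosine analysis
takes consecutive stay-trial state pairs, averages the shift vectors by the
earlier trial's outcome, and bootstraps single-trial shifts for the CI.

## Value decoding and meta-learning metrics

Per-bin linear readouts are LASSO regressions of the per-trial switch
value on the population rate vector, trained with
leave-one-proximity-group-out cross-validation (groups = visits remaining
until the next switch, capped at 8; the cap is our choice — deeper trials
are lumped). Switch trials and stays from incomplete final bouts never
enter training; they are decoded by the average of the fold models, and
every held-out stay trial is decoded only by the model that excluded its
group (audited structurally on every run). The penalty is chosen per fold
by inner 5-fold cross-validation on the training rows. Held-out R² is
computed on pooled predictions (not per-fold averages), against both the
current and the next trial's value; the last trial of each session is
dropped from next-trial scoring. Decoded per-trial scalars: pre-choice
(bins 1–4), post-choice (bins 5–8), outcome (bins 9–11), bin 1 and bin 8.

The metrics are pure differences of these scalars (hence invariant to any
constant offset in decoded values): repletion (switch-out pre-choice minus
next same-patch switch-in post-choice), depletion (first-stay post-choice
minus rewarded switch-in post-choice), outcome effect (outcome minus
bin-8), value update (next-trial bin-1 minus bin-8), their
omission-minus-reward deltas, and the single-visit variant in which the
switch-out trial replaces the first stay. Confidence intervals are
percentile bootstraps over event pairs (10,000 iterations by default).
Choice prediction follows the single-predictor logistic model with an
accuracy-optimized threshold and balanced (sensitivity/specificity-
averaged) accuracy; note that when predicting a *stochastic* agent's
choices from its own value, balanced accuracy is ceilinged by the softmax
temperatures — the decoder can only reach the behavioral ceiling, not 1.

## Known limitations

* The rewarded single-visit update is slightly negative in the model's
  latents (the one-step prospective depletion does not engage while the
  partner port is unvisited, so the reward's effect dominates), whereas
  omission-side updates and all early-versus-late contrasts behave as
  expected. A generator that encodes the fitted model's latents inherits
  this; reproducing a rewarded-positive single-visit update would require
  a latent the behavioral model does not produce.
* Decoded-variance levels on synthetic data exceed typical recordings (see
  gain-scale note above); directional and cross-regime contrasts, not
  absolute R², are the meaningful comparisons.
* Cross-animal mixed-effects statistics are out of scope; the provided
  tests are per-dataset (two-proportion Z, rank-sum, bootstrap).

## Problem sizes used by the test suite

Unit tests run on two-session days (250–300 trials) with 40-neuron
populations. The acceptance-style checks use the study-scale conditions:
5 × 300-trial days, 100-neuron populations, five optimizer multi-starts
for the headline recovery, an 80-neuron balanced panel with 10
cross-validation repeats for categorization, and ten seeded replicate
pairs (late vs early regime) at full day scale with reduced bootstrap
counts for the direction suite. Parameter-recovery batteries use six
two-session days per generative condition with two multi-starts per fit.
These sizes are the package's chosen trade-off between statistical
resolution and a test suite that runs in minutes.
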