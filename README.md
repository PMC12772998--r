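# metaforage

Simulation and analysis tools for studying **meta-learning in a depleting
spatial bandit**: how a forager shifts from recency-weighted reward learning
to rule-based value inference when the environment imposes a
depletion–repletion rule, and how that shift is expressed in (synthetic)
prefrontal population activity.

The package is aimed at computational neuroscientists and behavioral
modelers who want a fully closed-loop, desk-scale testbed: every analysis
can be exercised end-to-end on simulated agents and synthetic Poisson
spiking populations, with no external data.

## What it implements

**Task environment.** Three Y-shaped patches, two reward ports each, with
nominal reward probabilities p(R) ∈ {0.2, 0.5, 0.8} (exactly one best
patch, never a {0.8, 0.8} pair). Within-patch alternation multiplies a
port's effective p(R) by a discount (default 0.8) per re-visit; switching
patch restores the departed patch to nominal. Consecutive visits to the
same port are never rewarded.

**Behavioral model.** A Beta–Bernoulli learner per port with pseudo-counts
α, β (initialized to 1 per session) and port value Q = α/(α+β). A reward
increments α by 1; an omission increments β by

    (1 − μ) / (1/d − μ),   μ = (α + 1)/(α + β + 2),

where d is the agent's running depletion estimate, starting at 1 and
multiplied by a fitted **depletion factor** at each same-port re-visit (the
increment reduces to +1 at d = 1 and vanishes as d → 0: an omission at a
fully depleted port is uninformative). Non-chosen ports decay toward 1
(forgetting). Choices follow a structured softmax over integrated patch
values

    V_stay = β_stay·Q + b_stay,   V_left = β_go·Q + b_turn,   V_other = β_go·Q,

with a second softmax (β_port) over ports when switching. The decision
variable is the **switch value**, max V_alternative − V_current. Fitting is
by maximum likelihood (BFGS multi-start in transformed space, compiled
likelihood) per day, or hierarchically across days by EM with a Laplace
approximation to the day-level posteriors.

**Synthetic neural populations.** Poisson spiking whose log-rate is
baseline + journey×goal-progress tuning + value gain × switch value, with
value-gain profiles shared at one of four generality levels (progression /
action / patch / journey) or absent. 8 run-period progression bins plus 3
outcome-period bins per trial, and an optional 50-sample fine-time grid for
state-space analyses.

**Analyses.** Poisson GLMs (48 journey×progression indicators, value×bin
interactions at four granularities, L1-penalized, repeated 10-fold CV) with
rank-sum/Holm categorization of value-coding generality; PCA navigation and
pre-move subspaces with post-outcome shift-cosine geometry; per-bin LASSO
decoding of switch value with leave-one-proximity-group-out
cross-validation (switch trials never trained on); and the decoded-value
meta-learning metrics — neural value repletion, depletion, outcome effect,
value update, their reward/omission deltas, single-visit analysis, and
switch/stay prediction by balanced accuracy.

## Worked example

```r
library(metaforage)

maze  <- maze_config()                       # high patch {0.5, 0.8}, discount 0.8
agent <- agent_params(depletion_factor = 0.8, decay = 0.05)
day   <- simulate_agent(maze, agent, n_sessions = 5,
                        trials_per_session = 300, seed = 42)

fit <- fit_day(day$trials, maze, n_starts = 3)
fs  <- summarize_foraging(day$trials, maze)

spec     <- make_coding_spec(n_neurons = 60, seed = 42)
pop      <- generate_population(day$trials, day$trace, spec, seed = 43)
decoders <- train_decoders_cv(assign_bins_and_groups(pop, "progression"),
                              seed = 44)
decoded  <- decoded_summary(decoders)
choice   <- predict_decisions(decoded$pre, decoded$is_switch,
                              n_boot = 2000, seed = 45)
mm       <- metalearning_metrics(decoded, n_boot = 2000, seed = 46)
```

Output:

```
recovered depletion factor: 0.763 (generative 0.8)
reward rate: 0.419   P(switch | reward): 0.319
held-out decoding R^2, pre-choice bins: 0.91
balanced switch/stay accuracy: 0.635 (95% CI 0.593-0.673)
neural value repletion: 0.092 (95% CI 0.066-0.120, n = 604)
```

Reading this: the refit of the agent's own choices recovers the generative
depletion factor (0.76 vs 0.8) rather than drifting to 1 — the signature
that the choices carry the rule. The decoders read the latent switch value
from spike counts on held-out proximity groups; the mean pre-choice readout
predicts single-trial switch/stay decisions above chance (bootstrap CI
entirely above 0.5); and decoded value drops from patch departure to the
next re-entry into the same patch (positive repletion) before any outcome
is delivered.

A full multi-stage run (simulate → fit → neurons → GLM → geometry → decode
→ metrics) is available through `run_pipeline(pipeline_config(seed), dir)`,
which writes CSV/JSON artifacts plus a manifest and is byte-reproducible
from its configuration.

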