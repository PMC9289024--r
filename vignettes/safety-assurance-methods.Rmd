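---
title: "Auditing and retraining an RL sepsis policy under safety constraints"
author: "sepsafe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing and retraining an RL sepsis policy under safety constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Reinforcement-learning treatment recommenders for sepsis learn, from
recorded ICU trajectories, a policy mapping a patient state to intravenous
fluid and vasopressor doses. Before such a system can be trusted it needs
explicit safety evidence: does it recommend *obviously dangerous* decisions
less often than the clinicians whose data trained it, and can it be
retrained to avoid them without losing value? `sepsafe` implements that
audit-and-retrain loop end to end: hazard-scenario flagging, human-vs-AI
proportion tests, feature attribution of unsafe clinician behaviour, reward
reshaping with Q-learning retraining, and off-policy value estimation — all
exercised on a synthetic ICU cohort with known ground truth, because the
clinical database the methodology targets is credentialed-access.

## Hazard scenarios

Four scenarios encode under- and overdosing of the two drugs. Each pairs an
*at-risk* condition on the patient state with an *unsafe action* condition
on the doses given that step:

| id | at risk | unsafe action |
|----|---------|---------------|
| A | MAP < 55 mm Hg | no vasopressors and fluids ≤ 20 mL/h |
| B | MAP > 95 mm Hg | vasopressors > 0.65 µg/kg/min |
| C | MAP ≤ 55 and CVP ≤ 5 mm Hg | no fluids |
| D | MAP ≥ 75, balance > 10 L, CVP ≥ 15 | fluids > 240 mL/h |

Comparators are applied literally (A strict, C inclusive, etc.), fluid
rates are per-step volumes divided by the step duration, and every
threshold is configuration: because there is no consensus cut-off for
hypotension or hypertension, the audit is run across a grid of MAP
thresholds (defaults 45–60 mm Hg for A/C, 85–105 for B, 2.5 mm Hg steps),
with a per-threshold significance trace. A step unsafe under several
scenarios counts once in the any-scenario union and once per scenario in
per-scenario reports.

Policies are audited at the *same* at-risk steps as the clinicians, with
recommended action bins resolved to their within-bin median dose (bin 0
resolves to exactly zero, so "no fluids"/"no vasopressors" conditions are
exactly decidable for a policy). Keeping the at-risk denominator `N`
identical across agents is what licenses the test below.

## The statistical comparison

Unsafe decisions by either agent among the `N` at-risk steps are modelled
as Bernoulli counts with a common denominator. The statistic is

$$z = \frac{\hat p_{AI} - \hat p_{Human}}
           {\sqrt{\hat p(1-\hat p)\cdot 2/N}},\qquad
  \hat p = \tfrac12(\hat p_{Human} + \hat p_{AI}),$$

standard normal under the null for large `N`; the default sidedness is
one-sided lower (the AI takes *fewer* unsafe decisions), two-sided is a
flag. Degenerate pooled proportions (0 or 1) give z = 0 for equal counts
and ±∞ otherwise. No multiplicity adjustment is applied across a threshold
sweep by default — the per-threshold trace is itself the object of interest
— but a Bonferroni option exists. Calibration is verified in the test
suite: under a simulated null the two-sided rejection rate at α = 0.05
lands in [0.04, 0.06], and a planted 0.5 vs 0.4 gap at N = 1000 is detected
with power above 0.9.

## Feature attribution

For each scenario, a gradient-boosted tree ensemble (60 rounds, depth 3,
learning rate 0.2, single thread for reproducibility) predicts whether the
clinician took the unsafe action at an at-risk step, from the observable
features. TreeSHAP values give signed per-observation attributions; the
report ranks features by mean |SHAP| normalized to the top feature and
attaches the sign of the feature–SHAP correlation ("low SOFA pushes toward
unsafe"). These attributions describe clinician behaviour in the data, not
causal claims.

## MDP, reward reshaping, retraining

Timesteps are clustered (k-means on standardized features, k configurable;
desk-scale analyses use k ≈ 20, the full-scale lineage uses several
hundred) into patient states, plus absorbing survival/death terminals.
Doses are discretized per drug into a zero bin plus quartiles of the
non-zero doses, composing 25 actions. The MDP is the empirical transition
table; state-action pairs observed fewer than `min_count` times are
inadmissible, so no policy can recommend essentially untried dose
combinations.

The base reward is terminal only: ±100 on survival/death (magnitude and
γ = 0.99 are configuration, adopted from the AI-Clinician lineage). Safety
reshaping subtracts an intermediate penalty from each state-action pair
proportional to the fraction `f(s,a)` of its observed instances flagged
unsafe under any scenario: `r(s,a) = −P·f(s,a)` with `P = 30` points by
default. The expected-penalty form is deliberate: clusters aggregate
heterogeneous steps, and `−P·f` preserves the mean of the instance-level
penalty; a binary majority-flagged mode is available. Overlapping scenarios
contribute once (union), and `P = 0` reproduces the original reward
bit-for-bit, which the pipeline exploits as an invariant (a penalty-0
retrain must emit the original policy).

Policies are learnt by tabular Q-learning over the observed transition
list, replayed in seeded shuffled order with learning rate
`α0 / (1 + decay·n(s,a))`, stopping when the largest net Q change over a
full sweep falls below `tol` (default 1e-4). The net-per-sweep criterion
matters: with stochastic successors the per-update change is proportional
to the learning rate, not the residual, and would never reach a tight
tolerance, while the net change over a sweep cancels sampling noise around
the empirical fixed point. Because Q-learning and value iteration on the
same empirical table share that fixed point, an exact Bellman solver
(`exact_solve()`, sup-norm 1e-10) serves as an independent oracle: on
dozens of random MDPs the greedy policies must coincide, and they do. Ties
in the argmax break to the lowest action index — the lowest composed doses,
a deliberately conservative convention.

## Off-policy evaluation

Policy values are estimated by weighted (self-normalized) importance
sampling over whole stays, with the behaviour policy estimated from
per-state action frequencies (additive smoothing λ = 0.01 over observed
actions) and greedy policies softened to `1−ε` on the greedy action
(ε = 0.01). WIS was chosen over plain importance sampling for variance
control; its estimate is always inside the observed return range, and
evaluating the behaviour policy against itself returns the plain mean
discounted return exactly — both enforced as identities in the tests.
Confidence bounds come from a stay-level bootstrap (stays are the
independent units) with B = 2000 resamples, reported as median and IQR.
Values are computed on the *unpenalized* reward scale by default so agents
are comparable; under the penalized scale the safe policy's value is lower
by construction.

Two caveats are documented rather than hidden. First, WIS against a
near-deterministic target concentrates weight on stays that happen to match
the greedy recommendations — typically short ones — so desk-scale values
are noisy and the bootstrap IQR must be read alongside the point estimate.
Second, this is also why the pipeline default `min_count` is 50 rather than
the module default 5: with only ~20 states and ~30k steps, an argmax
allowed to pick five-times-tried actions chases sampling noise in their
estimated outcomes and ends up recommending actions the behaviour almost
never takes, destroying importance-sampling overlap entirely (values pinned
to −100 by a handful of short death trajectories). Raising the
admissibility threshold is a variance-control and safety choice: recommend
only what has actually been tried often enough to judge.

## The synthetic cohort

The generator emulates the statistical structure the audit needs, with
every coefficient in `sim_config()`:

* 4-hour timesteps, 18 per stay (72 h of resuscitation); per-hour
  thresholds are converted via `step_hours`.
* A latent severity per stay (Beta(2,3), small Gaussian drift, worsening
  under untreated hypotension) drives MAP drain, oliguria, lactate, SOFA
  and the death hazard. Severity is *not* emitted: the state model sees
  only observables, a realistic partial-observability constraint.
* MAP follows a homeostatic pull toward 78 mm Hg plus a concave fluid
  response (log1p, attenuated at high severity — vasoplegia), a linear
  vasopressor response, severity drain, and noise, clipped to a physiologic
  range. CVP is a baseline plus ~1 mm Hg per litre of cumulative balance.
  Urine output scales with a per-stay renal-function factor, falls with
  severity and rises with MAP above a 55 mm Hg perfusion floor. Cumulative
  balance is exactly Σ(inputs − urine), an invariant the tests enforce.
* The behaviour policy targets MAP 65–90 with dose ranges typical of
  resuscitation (boluses of 600–1600 mL per 4 h in severe hypotension,
  severity-scaled maintenance fluids); whenever a scenario's at-risk
  condition holds it is replaced by that scenario's unsafe action with a
  configured propensity. Defaults (A 0.5, B 0.03, C 0.5, D 0.35) sit near
  the unsafe-decision rates reported for the reference clinical cohort, and
  a binomial-recovery test checks the realized rates match the
  configuration.
* Death is a per-step logistic hazard in severity, hypotension exposure and
  fluid overload (>10 L), calibrated to ~25% episode mortality; surviving
  to the end of the window is labelled survival. This collapses "90-day
  survival" to survival of the simulated episode — the simulator does not
  model post-ICU time, a documented limitation.

What passing tests on this cohort do and do not show: they demonstrate that
the *pipeline machinery* is correct (flags count what they should, the
tests are calibrated, retraining responds to the penalty in the right
direction, estimators satisfy their identities) under data whose ground
truth is known. They do not establish clinical performance: the simulator
has no comorbidities, no missingness, no informative measurement timing,
and its behaviour policy is far more homogeneous than real clinicians.
Scenario-D propensity is applied on the pre-action fluid balance while the
audit reads the emitted post-action balance, so D's realized rate tracks
its configured propensity only approximately.

## Problem sizes and numerical choices

Default analyses use 2000 stays (~32k timesteps), k = 20 states, 25
actions, B = 2000 bootstrap resamples; the whole pipeline runs in well
under a minute and the test suite exercises it end to end, including a 50-
MDP Q-learning-vs-value-iteration equivalence sweep and a 10,000-replicate
z-test calibration. k-means uses 10 restarts under a fixed seed;
standardization constants come from the fitting cohort only; constant
features standardize with SD 1. Quantile bins use the default empirical
quantile (type 7) with left-closed bins; degenerate dose columns fall back
to fewer bins with a warning, keeping the composed index space stable. All
stage seeds derive deterministically from one master seed, and rerunning
any configuration reproduces every output byte-for-byte.
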