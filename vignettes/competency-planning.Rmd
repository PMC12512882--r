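---
title: "Planning competency-building activities: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning competency-building activities: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decision problem

A digital coach prepares daily smokers for a quit attempt over five short
sessions. In each session it proposes one activity from a catalog of 53:
44 *preparatory* activities that directly build six expert-identified
competencies (practical skills, clear future identity, motivation,
knowledge, and insights into personal strengths and weaknesses), and 9
*persuasive* activities that instead target one of nine usefulness
beliefs smokers hold about what helps quitting. `quitprep` implements the
model that chooses these activities, the estimation of its dynamics from
micro-randomized interaction logs, and the analyses that quantify what
each model component contributes.

## The factored MDP

The model is a Markov decision process $\langle S, A, R, T, \gamma\rangle$.

**State.** A state couples two factored parts:

* six competency levels on the grid $\{0, 1/3, 2/3, 1\}$ ($4^6 = 4096$
  configurations), which evolve *deterministically*, and
* three binary user-inquired features — two usefulness beliefs and energy,
  thresholded at their sample means — which evolve *stochastically*
  ($2^3 = 8$ configurations).

The full space has $8 \times 4096 = 32768$ states, indexed mixed-radix
with the user-feature bits high-order (`state_space()`, `encode_state()`).
Internally the grid uses exact thirds; 0.33/0.67 in printed material are
display roundings. Working in exact thirds avoids accumulating rounding
error over repeated updates.

**Actions.** The 53 catalog activities. For dynamics estimation they are
grouped into 14 *action groups*: the five k-means clusters of preparatory
activities (clustered on smokers' ratings of what the activities teach,
`cluster_preparatory_activities()`) and one singleton group per persuasive
activity.

**Effort and reward.** Self-reported effort on 0–10 is mapped
piecewise-linearly onto $[0,1]$ with the population mean at 0.5
(`scale_effort()`). An activity's contribution $cont_{a,j} \in [0,1]$ to
competency $j$ scales with effort; the snapped *possible contribution*
$pc_j = \mathrm{snap}(cont_{a,j} \cdot e)$ is credited only up to the
remaining headroom:

$$R(s, a) = \sum_{j=1}^{6} \min\{pc_j,\; 1 - comp_j\} \in [0, 6].$$

Persuasive activities have all-zero contributions and hence zero reward.
Competency levels update as
$comp_j \leftarrow \mathrm{snap}(\min\{comp_j + e \cdot cont_{a,j},\, 1\})$
(`update_competencies()`): capped first, then snapped, so the update
honours the level ceiling and never decreases a level.

**Transitions.** The three binary features transition independently of one
another, with probabilities estimated per (feature, current bit, action
group) from the log (`fit_transition_model()`); the joint next-feature
distribution is the product of the per-feature Bernoullis. Competency
transitions are deterministic given the mean effort of the person's
feature configuration and the activity's group (`fit_effort_model()`).
The discount factor defaults to $\gamma = 0.85$, favouring early
competency gains.

### Numerical choices

* **Snap ties.** Raw values exactly at $1/6$, $1/2$, $5/6$ are resolved
  *upward* by default. The choice is observationally rare (it needs
  $cont \cdot e$ to hit a midpoint exactly) but must be fixed for
  reproducibility; upward resolution is consistent with the cap-at-one
  update and never under-credits reward. `ties = "down"` is available.
* **Reward source.** Reward is computed from the snapped possible
  contribution ($\sum_j \min\{pc_j, 1-comp_j\}$), not from the realized
  level delta of the update; the two can differ by one grid step when the
  current level's snap interacts with the increment. Both quantities are
  exposed (`compute_reward()`, `update_competencies()`); the MDP uses the
  formula above.
* **Estimation fallbacks.** Effort cells with no observations fall back
  to the action-group mean; unseen transition cells fall back to 0.5. No
  further smoothing is applied by default — the estimated functions are
  the plain empirical means — and fallback cells are flagged in the
  fitted objects.

## Feature selection

Of the eleven user-inquired features (nine beliefs, energy, time), three
are kept. Selection is greedy, in the spirit of the G-algorithm: a
candidate's score is the stratum-size-weighted mean absolute difference
in mean scaled effort between candidate = 0 and candidate = 1, stratified
by the configurations of already-selected features crossed with action
group (`score_feature_split()`, `select_features()`). "Effort-based
Q-values" are thus read as immediate expected effort (a bandit-horizon
Q): effort is the quantity the selection is meant to explain, and
multi-step Q-values would require the very transition estimates the
reduction precedes. No significance test is applied to splits; ties break
to the lowest feature index. Both choices are deliberate simplifications
and are documented in the scoring output.

## Planning

`gauss_seidel_vi()` computes an $\varepsilon$-optimal policy
($\varepsilon = 0.001$) with asynchronous in-place sweeps from a zero
initialization in enumeration order. The successor structure stays sparse
— at most 8 successors per state-action, never a $32768^2$ matrix — and
the sweep kernel is compiled (Rcpp), making a full sweep roughly
$32768 \times 53 \times 8 \approx 1.4\times10^7$ fused operations. The
default stopping rule is the span-seminorm bound
$\mathrm{span}(V_{k} - V_{k-1}) < \varepsilon(1-\gamma)/\gamma$ (the MDP
toolbox convention, which certifies an $\varepsilon$-optimal greedy
policy); a plain sup-norm criterion is available and is what the test
suite uses when comparing value functions against a brute-force
synchronous oracle. Q-ties break to the lowest action id. The no-repeat
advisor (`next_best_action()`) proposes the highest-Q activity not yet
proposed to that person.

## The ablation simulation

`make_policy()` builds the six policies compared in the ablation:
value iteration on the full model (`full`); with learned next-feature
transitions replaced by uniform ones (`no_next_uf`); the immediate-reward
contextual bandit (`myopic`); a bandit seeing only competency levels,
with effort marginalized over feature configurations using their observed
weights (`ec_only`); the rule that picks randomly within the preparatory
cluster with the highest expected effort given the current features
(`uf_only`); and uniform random preparatory choice (`random`).

`simulate_cohort()` runs 1000 simulated people for five proposed
activities. Everyone starts with all competencies at zero and a feature
configuration drawn from the distribution observed in first sessions.
The environment is identical for every policy: the *full* learned models
drive realized effort (the mean scaled effort of the person's cell — a
deterministic quantity, matching the population-level nature of the
model; a truncated-normal sampled-effort mode exists as a sensitivity
flag) and the feature transitions. Random draws are pre-allocated per
person, step, and feature, so two policies that choose the same actions
see bit-identical feature trajectories. The no-repeat rule applies at the
individual-activity level for all variants; random variants sample
without replacement. Dropout is not simulated.

The outcome, *fraction of expert competencies built*, is the cohort mean
of $\sum_j comp_j / 6$ — normalized by the six-competency ceiling. An
alternative normalization by the best total achievable within the horizon
at unit effort (a greedy bound) is available via
`normalize = "reachable"`; the ceiling reading is the default because it
is the simplest interpretation of the fraction and leaves curves
comparable across horizons.

`robustness_resample()` refits, re-plans, and re-simulates on stratified
95% subsamples per action; `gamma_sweep()` re-plans across discount
factors. At $\gamma = 0$ the swept policy reproduces the myopic variant
exactly, a useful internal consistency check.

## Belief-change analysis

For every persuasive activity, the targeted belief is compared before and
after assignment with a Bayesian paired test (`paired_best_test()`):
Kruschke's BEST model on the differences — Student-t likelihood with
location $\mu$, scale $\sigma$, normality $\nu$ — with the broad
data-scaled priors popularised by the Bayesian First Aid package
($\mu \sim N(\bar{x}, (1000\,s_x)^2)$,
$\sigma \sim U(s_x/1000, 1000\,s_x)$, $\nu - 1 \sim \mathrm{Exp}(1/29)$),
sampled with JAGS. Defaults are 4 chains of 5000 draws after 1000
warm-up iterations, with the split-chain potential scale reduction for
$\mu$ reported. Summaries are the posterior mean and SD of $\mu$, the
95% highest-density interval (narrowest sorted-window interval,
`hdi()`), and $P(\mu > 0)$. Cohen's $d$ on paired differences and
Cohen's $h$ for proportion contrasts accompany the table. No
multiple-testing correction is applied across the nine activities — each
is reported as its own analysis.

## What the synthetic generator emulates — and what it does not

`generate_mrt_log()` produces interaction logs with the statistical
structure the pipeline assumes, so every stage is testable against known
ground truth without the original study data:

* 542 people, up to five sessions, uniform randomization over the
  14 action groups (then uniform within a cluster);
* raw effort from a discretized truncated normal per (feature
  configuration, group) cell; cell means are additive in the three
  informative features with shifts of 2.5, 1.0, and 0.7 raw points
  (a deliberately dominant first feature, so selection tests have a
  well-defined planted answer) and the within-cell SD is solved
  numerically so the realized population moments match the calibration
  targets of mean 5.58 and SD 2.86;
* binary feature dynamics with persistence (staying at 1 is more likely
  than jumping to 1), plus a boost and an upward raw-scale drift of the
  targeted belief after persuasive activities;
* attrition: sessions 1–2 always attended, later sessions continued with
  probability 0.86, which yields roughly 64% session-5 completion and an
  expected sample count near 1710.

Raw feature values are drawn *conditional on* latent bits with a gap at
the threshold (beliefs in $-10..-1$ or $1..10$; energy/time in $0..4$ or
$6..10$), so that sample-mean binarization reproduces the generative bits
exactly and parameter-recovery comparisons are well-posed.

The generator is deliberately not a behavioural model of smokers: raw
belief dynamics within a half-range are uniform, features are
conditionally independent given the bits, there are no individual
differences, and effort has no session trend. Passing tests on this data
therefore demonstrate that the *pipeline* is correct and consistent —
estimators converge to the generating parameters, planning improves on
ablated policies when features genuinely modulate effort — not that the
learned policies would perform identically on real study populations.

## Problem sizes used in the shipped tests

The test suite and acceptance script run the full 32768-state planner
with the complete 53-activity catalog, cohort simulations with 1000
people, parameter recovery on logs of $10^4$ samples (with a convergence
check at $10^5$), 20-replicate feature-selection studies at study-scale
logs, and MCMC with 2–3 chains of 1500–2000 retained draws per analysis.
These sizes keep each analysis at the scale of the study itself while
remaining quick to re-run; the defaults in the package (4 × 5000 draws,
for instance) are the ones intended for reported analyses.

## Known limitations

* Transitions are population-level and per-feature independent; no
  individual- or trait-level adaptation.
* The effort model conditions jointly on all three selected features
  (8 cells per group), which is faithful but data-hungry; with study-size
  logs several cells rely on the group-mean fallback.
* The span-criterion stopping rule certifies policy quality, not value
  accuracy; use the sup-norm criterion when values themselves matter.
* The maximum-error parameter-recovery guarantee at $10^4$ samples is
  tight: with 112 effort cells of ~90 observations each, worst-cell error
  concentrates around 0.06–0.09 even for a correct estimator; per-cell
  accuracy at the 0.05 level needs roughly $10^5$ samples.
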