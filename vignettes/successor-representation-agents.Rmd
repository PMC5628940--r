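---
title: "Successor-representation agents and gridworld revaluation tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Successor-representation agents and gridworld revaluation tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridsr)
```

## The problem

A long-standing question in the computational study of decision-making is
how flexible, goal-directed ("model-based") behaviour can be produced by
circuitry whose best-understood learning rule is a model-free
temporal-difference (TD) update. The successor representation (SR) is the
standard bridge: the value function under a policy $\pi$ factorises as

$$V^\pi(s) = \sum_{s'} M^\pi(s, s')\, w(s'),$$

where $M^\pi(s,s') = \mathbb{E}\big[\sum_t \gamma^t \mathbb{1}(s_t = s')
\mid s_0 = s\big]$ is the expected discounted future occupancy of $s'$
from $s$, and $w(s')$ is (at convergence) the policy-averaged one-step
reward in $s'$. Because the occupancy matrix caches *where the agent will
be* separately from *what is worth having*, a purely local change in reward
can update values globally through a single weight change — some, but not
all, of the flexibility of full model-based planning.

This package implements a family of tabular agents spanning that spectrum,
together with the gridworld revaluation tasks that separate them
behaviourally:

* **`onestep_td`** — TD value learning on a punctate state code, plus one
  step of lookahead to turn $V$ into action values. The model-free foil.
* **`sr_td`** — the original SR: $M$ learned by a TD rule on occupancy
  rows, $w$ by linear-TD on those rows as features.
* **`sr_mb`** — recomputes $M = (I - \gamma T^\pi)^{-1}$ before every
  choice from a learned one-step model: deterministic grid physics, an
  observed set of available actions per state, and a delta-rule estimate
  $\pi(a\mid s)$ of the agent's own past choices.
* **`sr_dyna`** — a state-action occupancy matrix $H$ learned on-policy
  online (SARSA-style) and re-learned *off-policy* by replaying stored
  transitions, each replay bootstrapping through the currently best
  continuation action $a^{*} = \arg\max_{a'} \sum H(s'a', \cdot)\,w$.
* **`dyna_q`** — tabular Q-learning plus the same replay machinery,
  operating directly on cached action values.

## Tasks and their logic

All three revaluation tasks stage a local change in the world and ask
whether the agent's *first* post-change policy, derived from its recorded
value table without any further training trajectories, is the optimal one.

* **Latent learning** (`run_latent_learning`): reward-free exploration,
  then the reward at `R1` is raised to 10 and experienced only in
  isolation (20 single-step collect probes at `R1`). Passing requires
  structural knowledge transferred from the reward-free period.
* **Detour** (`run_detour`): exploration, reward at `R`, five training
  trials from `S`, then a wall at `B` on the trained path, experienced only
  by being placed in the cell immediately left of the wall 40 times.
  Passing requires the *transition* change to propagate to distal values.
* **Policy revaluation** (`run_policy_revaluation()`): the full latent
  procedure at `R1`, 20 trials alternating starts `S1`/`S2`, then a larger
  reward (20) appears at `R2`, off the entrenched policy's paths,
  experienced in isolation. Passing requires value estimates that are not
  conditioned on the stale behavioural policy.

The categorical profile these produce — which architecture passes which
task — is the package's headline output (`flexibility_matrix()`):
occupancy caching (`sr_td`) survives reward revaluation but not transition
or policy revaluation; choice-time recomputation from a one-step model
(`sr_mb`) additionally survives transition revaluation but remains
on-policy and fails policy revaluation; off-policy replay (`sr_dyna`,
`dyna_q`) solves everything *given enough replay* and degrades gracefully
(`sr_dyna` to `sr_td`-like behaviour, `dyna_q` to a model-free learner)
when replay is scarce.

## Environment semantics

Mazes are ASCII maps (`#` wall, `.` open, `S`/`1`/`2` starts, `R`/`r`/`Q`
reward markers, `B` future barrier). Two choices deserve emphasis:

* **Reward sites are terminal from the outset.** Cells carrying a reward
  marker offer only the `collect` action at all times; their magnitude
  starts at 0 and is later *raised* by the protocol. Exploration is
  therefore episodic (entering a site collects 0 and restarts the walk),
  occupancy rows of sites stay punctate, and the probe phases produce
  punctate feature vectors. This matters: if reward cells were ordinary
  corridor cells before the reward appears, the random walk would pass
  through them, the first probe's feature vector would spread weight over
  the whole neighbourhood, and the implied policy near the reward would
  lose its gradient.
* **A wall inserted mid-run keeps its state index** (with an empty action
  set), so every agent's matrices keep fixed dimensions across the
  manipulation; blocked actions are *unavailable*, not no-ops, and agents
  learn availability only from direct observation of the cell they occupy.

The shipped fixtures are synthetic layouts that reproduce each task's
topological structure — unique shortest paths from the relevant starts,
the barrier on the trained route with a longer alternate corridor, the
large late reward in the far corner — at the smallest sizes at which the
categorical contrasts are stable. Three scale and shape constraints bind.
First, the discount sets an upper bound on how much longer the path to a
larger reward may be: the policy-revaluation map satisfies
$d(S1{\to}R2) - d(S1{\to}R1) = 9 < \log 2 / \log(1/\gamma) \approx 13.5$,
so the larger reward genuinely dominates. Second, the *insufficient
replay* condition is relative to world size: with 40 post-change probe
steps and 10 replays per step, a world with few state-action pairs would
let even that small budget sweep the whole table several times. The
detour map therefore includes a large explorable room, keeping the number
of experienced pairs near the scale at which a ~10-replay budget performs
about one visit per pair. Third, the detour's local geometry separates
the probed cell from the junction: the cell immediately left of the wall
is a one-cell dead end behind the fork where the alternate corridor
branches off. For the choice-time recomputing agent the fork decision is
then structural — in the self-consistent on-policy solution the dead end
is worth exactly $\gamma V(\text{fork})$ and can never beat the alternate
branch — while for replay-starved agents the dead end, only two steps
from the trained reward-side corridor through the barrier, retains a
dominant stale value that a ~10-sample budget cannot erode. Placing the
fork at the probed cell itself, or lengthening the alternate corridor
with the fork at the probe, makes one or the other contrast depend on a
single noisy value comparison.

Exploration budgets scale with maze size at the original per-state rates
(250 steps per state for latent-style exploration, 100 for the detour),
so visit counts per state match the full-size procedures.

## Parameters

Defaults (`agent_params()`): $\gamma = 0.95$, $\epsilon$-greedy
exploration with $\epsilon = 0.1$ (ties broken uniformly), learning rates
$\alpha_w = \alpha_Q = \alpha_{sr} = 0.3$, policy rate $\alpha_\pi = 0.1$;
Dyna agents replay 10 samples between decisions and `k_post_change`
samples after a detected change (10 or 10000 for the insufficient /
sufficient conditions).

Choices made where the procedure was genuinely open:

* **Normalized weight updates.** The TD weight step divides the feature
  vector by its squared norm, $w \mathrel{+}= \alpha_w \delta\, f / (f
  \cdot f)$, so $\alpha_w$ is a proportional step size whatever the
  feature scale; the raw gradient (`weight_mode = "plain"`) is retained
  for sensitivity checks, and `"direct"` implements the delta rule on
  immediate reward used in the acquisition comparison.
* **Replay sampling.** Both between-decision replay and post-change bursts
  draw a state-action pair uniformly from the pairs present in the buffer,
  then one of that pair's samples by an exponential recency law over ranks
  ($\lambda = 1/5$, most recent first). An alternative we evaluated —
  exponential recency over the *whole* buffer — concentrates all replay on
  the last ~20 transitions; under it, two adjacent states' $H$ rows can
  inflate each other through the off-policy argmax (a reward-free
  self-reinforcing loop) and a small fraction of acquisition runs stall
  for $10^5$+ steps. The uniform-pair scheme makes replay a form of
  asynchronous value iteration over experienced pairs and shows no such
  pathology; it is the package default.
* **Change detection.** A post-change burst is triggered when the observed
  availability of the occupied state contradicts its last observation, or
  when a collect's realized reward deviates from the agent's current
  estimate for that pair by more than `change_tol` (0.01, i.e. 0.1% of
  the task's reward scale). Tying the reward trigger to the agent's
  *estimate* rather than to the last observed reward means each of the 20
  probe collects (whose prediction errors shrink geometrically,
  $10 \cdot 0.7^j$) re-triggers the burst while the change is still being
  learned, so the final bursts run with an essentially converged weight —
  matching a procedure in which the large replay batch follows the weight
  updates. A last-observation trigger would fire exactly once, with the
  weight only 30% learned, and the off-policy relearning of $H$ would then
  chase a reward estimate of 6 rather than 20.
* **SR-Dyna's online update** uses the SARSA error with the actually
  chosen next action (completed one step later, when that action is
  known); forced teleports (probe placements, trial starts) drop the
  pending pair rather than fabricating a fictitious successor action.
* **SR-MB's believed availability** is initialized to all four cardinal
  moves everywhere and corrected by observation of occupied states; a
  believed-available move whose physical successor would be off-grid is
  modelled as a bump (self-transition) until observed. Rewarded sites
  observed as collect-only contribute all-zero transition rows (mass
  exits to the absorbing terminal state), as do walled cells.

Numerical details: the terminal continuation is the zero vector in every
update; argmax ties anywhere are broken uniformly with the run's seeded
generator; value-iteration uses tolerance $10^{-10}$; the Neumann-series
route to $M$ truncates at 500 terms ($\gamma^{500} \approx 7\cdot
10^{-12}$); medians over runs use the lower median so the reduction is
always a value some run actually produced.

## Readouts

`median_value_map()` reduces each task's recorded value tables (for
Q-based agents, the maximum action value available in each state) to
per-state lower medians; `implied_policy()` points each open cell at its
best accessible successor (ties flagged); `policy_optimal()` passes a
policy only if greedily following it from the task's start reaches the
cell of *maximal* reward in exactly the shortest-path number of steps with
no tied cell en route — a cycle, a detour, or arrival at a lesser reward
all fail. `value_iteration()` provides the full model-based oracle, and
`policy_agreement()` compares an agent's implied policy against the
oracle's greedy policy on the states where the oracle's choice is unique.

## Acquisition comparisons

Two supplementary experiments use an episodic acquisition task
(`run_acquisition`: no exploratory period, trials from `S` to a reward of
10): TD versus direct delta-rule learning of the weights, and replay (20
samples per decision) versus no replay. Both comparisons are run at
parameters selected *per algorithm and condition* by the prescribed
grid search (`calibrate_acquisition()`: $\alpha_{sr}, \alpha_w \in \{0.1,
0.3, 0.5, 0.7, 0.9\}$, $\epsilon \in \{0.1, 0.3, 0.5\}$, $\alpha_Q$ over
the five rates for `dyna_q`), minimizing mean steps per trial over 20
trials; the search itself runs at 6 runs per setting with capped trials.
Fixed default rates are a poor substitute here: linear-TD control with
overlapping occupancy features can, at aggressive rates, dig a
negative-value moat around the reward that greedy behaviour never
recrosses, and a handful of such runs dominate the mean.

## What the simulations do and do not show

The generator produces exactly the study conditions described above:
deterministic mazes, a single scalar reward magnitude per site, reward
changes experienced in isolation, and categorical pass/fail readouts from
median value maps. Passing these tests shows that the implementations
realize the intended computational distinctions between the
architectures. It does not bear on stochastic or continuous environments,
on function-approximation variants of the SR, on realistic replay
dynamics or prioritization, or on quantitative fits to behavioural or
neural data — all outside this package's scope.

```{r example, eval = FALSE}
# the headline analysis (several minutes at 100 runs per cell)
fm <- flexibility_matrix(n_runs = 100, seed = 1)
fm[, ]

# one task, one agent, with the figure-style readout
res <- run_latent_learning("sr_td", n_runs = 100, seed = 1)
vm <- median_value_map(res)
render_policy_text(vm, res$world)
policy_optimal(implied_policy(vm, res$world), res$world, "S")
```
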