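# gridsr

Tabular reinforcement-learning agents built around the **successor
representation (SR)**, and the gridworld revaluation tasks that separate
model-free, SR-based, and fully model-based behaviour.

## The science

For a policy $\pi$ in a discounted Markov decision process, state values
factorise through the expected discounted future state occupancies:

$$V^\pi(s) = \sum_{s'} M^\pi(s,s')\,w(s'), \qquad
  M^\pi(s,s') = \mathbb{E}\Big[\textstyle\sum_{t\ge 0}\gamma^t\,
  \mathbb{1}(s_t=s') \,\Big|\, s_0=s\Big],$$

with $w(s')$ the one-step reward in $s'$. $M^\pi$ satisfies
$M^\pi = I + \gamma T^\pi M^\pi$, so it can be learned by a TD rule on
occupancy rows, computed in closed form as $(I-\gamma T^\pi)^{-1}$, or
re-learned off-policy from replayed experience. Where an agent sits on
that spectrum determines exactly which *revaluation* manipulations it can
solve on the first post-change trial:

| agent | latent learning | detour | policy revaluation |
|---|---|---|---|
| `onestep_td` (model-free foil) | fail | fail | fail |
| `sr_td` (cached occupancies) | **pass** | fail | fail |
| `sr_mb` (choice-time recomputation) | **pass** | **pass** | fail |
| `sr_dyna` / `dyna_q`, ample replay | **pass** | **pass** | **pass** |
| `sr_dyna`, scarce replay | **pass** | fail | fail |
| `dyna_q`, scarce replay | fail | fail | fail |

The package implements the five architectures, the three task protocols
(plus an episodic acquisition task), bundled maze fixtures, and the
analysis layer (median value maps, implied policies, a value-iteration
oracle, categorical verdicts, parameter sweeps).

## A worked example

```r
library(gridsr)

res <- run_latent_learning("sr_td", n_runs = 100, seed = 1)
vm  <- median_value_map(res)
round(vm[state_index(res$world, "R1")], 3)
#> [1] 9.992
render_policy_text(vm, res$world)
#> ##########
#> #>>>v#>>$#
#> #^##v#^#^#
#> #^#v<#^#^#
#> #^#v##^#^#
#> #^#>>>^#^#
#> #^####^#^#
#> #^<<<#^>^#
#> ##########
policy_optimal(implied_policy(vm, res$world), res$world, "S")
#> [1] "pass"
```

The value at the rewarded cell is $10\,(1-0.7^{20}) \approx 9.992$ — the
geometric approach of 20 probe updates at learning rate 0.3 — and the
implied-policy arrows trace the shortest path from `S` to the reward even
though the agent never travelled it after learning the reward: the
occupancy matrix cached during reward-free exploration carries the
structural knowledge. Replacing `"sr_td"` with `"onestep_td"` yields an
all-tied map away from the reward and a `"fail"` verdict.

The headline analysis runs every architecture through every task:

```r
fm <- flexibility_matrix(n_runs = 100, seed = 1)   # several minutes
fm[, ]
```

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gridsr.R", package="gridsr"))')" \
  run-task --task latent --agent sr_td --runs 100 --seed 1 --out out/
```

## Package layout

* `R/gridworld.R` — maze parsing, actions, transitions, rewards, walls,
  BFS oracle
* `R/sr_core.R` — occupancy matrices (states and state-actions), TD /
  closed-form / replay updates, value decoding
* `R/agents.R` — the five architectures and their helper operations
* `R/protocols.R` — the task procedures and the acquisition calibration
* `R/analysis.R` — medians, implied policies, verdicts, oracle, sweeps
* `src/engine.cpp` — the compiled protocol engine (same update rules,
  run at simulation speed)
* `inst/extdata/*.map` — bundled synthetic maze fixtures
* `vignettes/` — the methods vignette (model, assumptions, design
  choices, limitations)
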