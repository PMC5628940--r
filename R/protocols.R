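# The experimental procedures: the three revaluation tasks (latent learning,
# detour, policy revaluation) and the acquisition task, each executed for n
# independent seeded runs.

# Exploration budgets scale with maze size: the original procedures take
# 25000 (latent) and 10000 (detour) steps in 100-state worlds, i.e. 250 and
# 100 steps per state; the same per-state budget is applied to any fixture.
.auto_explore_steps <- function(world, per_state) {
  as.integer(per_state * world$n_states)
}

.run_seeds <- function(seed, n_runs) {
  set.seed(seed)
  sample.int(2147483646L, n_runs)
}

.phase_world <- function(world) list(type = "world", world = .world_compiled(world))

# execute one protocol (a fixed phase list) for n_runs independent seeds
.run_protocol <- function(task, kind, params, phases, n_runs, seed,
                          world_final, n_trials = 0L) {
  seeds <- .run_seeds(seed, n_runs)
  values <- vector("list", n_runs)
  lengths <- if (n_trials > 0L) matrix(NA_integer_, n_runs, n_trials) else NULL
  capped <- FALSE
  S <- world_final$n_states
  for (i in seq_len(n_runs)) {
    set.seed(seeds[i])
    st <- .agent_init_cpp(kind, S)
    res <- .run_protocol_cpp(kind, st, params, phases)
    values[[i]] <- res$values
    if (n_trials > 0L) lengths[i, ] <- res$trial_lengths
    capped <- capped || res$capped
  }
  structure(list(task = task, kind = kind, params = params,
                 n_runs = n_runs, seed = seed, run_seeds = seeds,
                 world = world_final, values = values,
                 trial_lengths = lengths, capped = capped),
            class = "gridsr_result")
}

#' @export
print.gridsr_result <- function(x, ...) {
  cat(sprintf("<gridsr_result: %s / %s, %d runs, %d record point(s)>\n",
              x$task, x$kind, x$n_runs,
              if (length(x$values)) length(x$values[[1]]) else 0L))
  invisible(x)
}

#' Latent learning task
#'
#' From the start marker `S` the agent takes an exploration period of random
#' movement through the rewardless maze (teleporting back to `S` on the --
#' nonexistent before reward -- terminals). The reward at `R1` is then set to
#' 10, and the agent learns about it in isolation: it completes a single
#' step, starting from `R1`, 20 times. The value table is recorded
#' immediately afterwards, before any further experience, so that a passing
#' agent must have transferred structural knowledge acquired during the
#' reward-free period.
#'
#' @param kind Agent kind (see [make_agent()]).
#' @param n_runs Number of independent runs.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param params [agent_params()].
#' @param world Task map (defaults to the bundled `latent` fixture; must
#'   carry markers `S` and `R1`).
#' @param explore_steps Exploration steps; `NULL` scales the original
#'   25000-step budget to 250 steps per maze state.
#' @return A `gridsr_result` with one recorded value table per run.
#' @export
run_latent_learning <- function(kind, n_runs = 500L, seed = 1L,
                                params = agent_params(),
                                world = task_map("latent"),
                                explore_steps = NULL) {
  for (m in c("S", "R1")) {
    if (!m %in% names(world$labels)) stop(sprintf("latent map must carry marker %s", m))
  }
  if (is.null(explore_steps)) explore_steps <- .auto_explore_steps(world, 250)
  w1 <- set_reward(world, "R1", 10)
  phases <- list(
    .phase_world(world),
    list(type = "explore", steps = as.integer(explore_steps),
         start = state_index(world, "S")),
    .phase_world(w1),
    list(type = "probes", at = state_index(w1, "R1"), n = 20L),
    list(type = "record"))
  .run_protocol("latent", kind, params, phases, n_runs, seed, w1)
}

#' Detour (transition revaluation) task
#'
#' After exploration, the reward at `R` is set to 10 and the agent completes
#' 5 trials from `S` that end at the reward, establishing a trained route.
#' A wall is then inserted at `B` -- validated to lie on the trained
#' (shortest) path -- and the agent learns about the blockade in isolation:
#' it completes a single step, starting from the cell immediately left of
#' the wall, 40 times. The value table is recorded immediately afterwards.
#'
#' @inheritParams run_latent_learning
#' @param world Task map with markers `S`, `R`, `B`.
#' @param explore_steps `NULL` scales the original 10000-step budget to 100
#'   steps per maze state.
#' @param trial_cap Step cap per trial (runs exceeding it are flagged).
#' @return A `gridsr_result`.
#' @export
run_detour <- function(kind, n_runs = 500L, seed = 1L,
                       params = agent_params(),
                       world = task_map("detour"),
                       explore_steps = NULL, trial_cap = 1000000L) {
  for (m in c("S", "R", "B")) {
    if (!m %in% names(world$labels)) stop(sprintf("detour map must carry marker %s", m))
  }
  if (is.null(explore_steps)) explore_steps <- .auto_explore_steps(world, 100)
  s0 <- state_index(world, "S")
  b <- state_index(world, "B")
  goal <- state_index(world, "R")
  d <- shortest_path_distances(world, goal)
  db <- shortest_path_distances(world, b)
  if (db[s0] + d[b] != d[s0]) {
    stop("fixture validation: barrier cell B does not lie on the trained shortest path")
  }
  probe_cell <- world$state_at[world$coords[b, 2] + 1L, world$coords[b, 1]]
  if (is.na(probe_cell)) stop("no open cell immediately left of the wall")
  w1 <- set_reward(world, "R", 10)
  w2 <- insert_wall(w1, "B")
  phases <- list(
    .phase_world(world),
    list(type = "explore", steps = as.integer(explore_steps), start = s0),
    .phase_world(w1),
    list(type = "trials", starts = s0, n_trials = 5L,
         cap = as.integer(trial_cap)),
    .phase_world(w2),
    list(type = "probes", at = probe_cell, n = 40L),
    list(type = "record"))
  .run_protocol("detour", kind, params, phases, n_runs, seed, w2,
                n_trials = 5L)
}

#' Policy revaluation task
#'
#' The agent first completes the entire latent-learning procedure with `S1`
#' as the start and `R1` as the reward (value 10). It then completes 20
#' trials that alternately start at `S1` and `S2` and end at `R1`,
#' entrenching a decision policy that moves away from the region of the maze
#' holding `R2`. The reward at `R2` is then set to 20 -- larger than `R1` --
#' and learned about in isolation via 20 single-step probes from `R2`. The
#' value table is recorded immediately afterwards; the optimal policy from
#' `S1` now leads to `R2`, but any agent whose occupancy predictions are
#' conditioned on the entrenched policy will still head for `R1`.
#'
#' @inheritParams run_latent_learning
#' @param world Task map with markers `S1`, `S2`, `R1`, `R2`.
#' @param explore_steps `NULL` scales to 250 steps per maze state.
#' @param trial_cap Step cap per trial.
#' @return A `gridsr_result`.
#' @export
run_policy_revaluation <- function(kind, n_runs = 500L, seed = 1L,
                                   params = agent_params(),
                                   world = task_map("policy_reval"),
                                   explore_steps = NULL,
                                   trial_cap = 1000000L) {
  for (m in c("S1", "S2", "R1", "R2")) {
    if (!m %in% names(world$labels)) {
      stop(sprintf("policy revaluation map must carry marker %s", m))
    }
  }
  if (is.null(explore_steps)) explore_steps <- .auto_explore_steps(world, 250)
  s1 <- state_index(world, "S1")
  s2 <- state_index(world, "S2")
  w1 <- set_reward(world, "R1", 10)
  w2 <- set_reward(w1, "R2", 20)
  phases <- list(
    .phase_world(world),
    list(type = "explore", steps = as.integer(explore_steps), start = s1),
    .phase_world(w1),
    list(type = "probes", at = state_index(w1, "R1"), n = 20L),
    list(type = "trials", starts = c(s1, s2), n_trials = 20L,
         cap = as.integer(trial_cap)),
    .phase_world(w2),
    list(type = "probes", at = state_index(w2, "R2"), n = 20L),
    list(type = "record"))
  .run_protocol("policy_reval", kind, params, phases, n_runs, seed, w2,
                n_trials = 20L)
}

#' Acquisition task (episodic learning speed)
#'
#' No exploratory period: the reward at `R1` is present (value 10) from the
#' first trial, and the agent completes `n_trials` episodes from `S`,
#' recording the number of steps each takes. Used to compare TD against
#' direct delta-rule learning of the reward weights, and to measure how
#' between-decision replay speeds acquisition.
#'
#' @inheritParams run_latent_learning
#' @param n_trials Episodes per run.
#' @param world Task map with markers `S` and `R1`.
#' @param trial_cap Step cap per trial (capped trials are flagged in the
#'   result).
#' @return A `gridsr_result` whose `trial_lengths` is an
#'   `n_runs x n_trials` matrix.
#' @export
run_acquisition <- function(kind, n_trials = 20L, n_runs = 500L, seed = 1L,
                            params = agent_params(),
                            world = task_map("acquisition"),
                            trial_cap = 1000000L) {
  for (m in c("S", "R1")) {
    if (!m %in% names(world$labels)) stop(sprintf("acquisition map must carry marker %s", m))
  }
  w1 <- set_reward(world, "R1", 10)
  phases <- list(
    .phase_world(w1),
    list(type = "trials", starts = state_index(w1, "S"),
         n_trials = as.integer(n_trials), cap = as.integer(trial_cap)),
    list(type = "record"))
  .run_protocol("acquisition", kind, params, phases, n_runs, seed, w1,
                n_trials = as.integer(n_trials))
}

#' Run a named revaluation task
#'
#' Dispatch wrapper over [run_latent_learning()], [run_detour()] and
#' [run_policy_revaluation()].
#'
#' @param task `"latent"`, `"detour"` or `"policy_reval"`.
#' @inheritParams run_latent_learning
#' @param ... Passed to the task function.
#' @return A `gridsr_result`.
#' @export
run_task <- function(task = c("latent", "detour", "policy_reval"),
                     kind, n_runs = 500L, seed = 1L,
                     params = agent_params(), ...) {
  task <- match.arg(task)
  fn <- switch(task, latent = run_latent_learning, detour = run_detour,
               policy_reval = run_policy_revaluation)
  fn(kind = kind, n_runs = n_runs, seed = seed, params = params, ...)
}

#' Grid-search calibration of acquisition parameters
#'
#' The acquisition comparisons (TD versus direct weight learning;
#' with-replay versus without-replay) are run at parameters selected per
#' algorithm and condition to minimize the mean total steps across trials,
#' by exhaustive search over a small lattice: `alpha_sr` and `alpha_w` in
#' \{0.1, 0.3, 0.5, 0.7, 0.9\} and `epsilon` in \{0.1, 0.3, 0.5\} for SR
#' agents, `alpha_q` over the same five values for `dyna_q`. Trials are
#' capped during the search so that degenerate settings cannot stall it.
#'
#' @param kind Agent kind.
#' @param n_trials,n_runs Search scale per setting.
#' @param seed Master seed.
#' @param base_params Parameters held fixed outside the searched lattice
#'   (e.g. `n_replay_per_step`, `weight_mode`).
#' @param world Acquisition map.
#' @param trial_cap Step cap per trial during the search.
#' @return The best [agent_params()] found, with the search table attached
#'   as attribute `search`.
#' @export
calibrate_acquisition <- function(kind, n_trials = 20L, n_runs = 6L,
                                  seed = 1L, base_params = agent_params(),
                                  world = task_map("acquisition"),
                                  trial_cap = 5000L) {
  rates <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  eps <- c(0.1, 0.3, 0.5)
  grid <- if (kind == "dyna_q") {
    expand.grid(alpha_q = rates, epsilon = eps)
  } else if (kind == "onestep_td") {
    expand.grid(alpha_w = rates, epsilon = eps)
  } else {
    expand.grid(alpha_sr = rates, alpha_w = rates, epsilon = eps)
  }
  score <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- base_params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][g]
    res <- run_acquisition(kind, n_trials = n_trials, n_runs = n_runs,
                           seed = seed, params = p, world = world,
                           trial_cap = trial_cap)
    score[g] <- mean(res$trial_lengths)
  }
  best <- which.min(score)
  out <- base_params
  for (nm in names(grid)) out[[nm]] <- grid[[nm]][best]
  attr(out, "search") <- cbind(grid, mean_steps = score)
  out
}
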