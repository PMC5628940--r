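# Reduction of simulated runs to the behavioural readouts: median value
# maps, implied policies, optimality verdicts against a value-iteration
# oracle, the agent-by-task flexibility matrix, and parameter sweeps.

# lower median: for even run counts take the lower of the two central order
# statistics, so the reduction is a value actually produced by some run and
# is bit-reproducible across platforms
.lower_median <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

#' Median value map of a task result
#'
#' Per-state (lower) median of the recorded value tables across runs.
#'
#' @param result A `gridsr_result`.
#' @param record Which record point to reduce (protocols here record once).
#' @return A numeric vector of length `n_states` (NA on walls) with the
#'   task's final `gridworld` attached as attribute `world`.
#' @export
median_value_map <- function(result, record = 1L) {
  stopifnot(inherits(result, "gridsr_result"))
  if (result$n_runs < 1L || length(result$values) == 0L) {
    stop("empty task result")
  }
  tabs <- vapply(result$values, function(v) v[[record]],
                 numeric(result$world$n_states))
  vmap <- apply(matrix(tabs, nrow = result$world$n_states), 1, .lower_median)
  attr(vmap, "world") <- result$world
  vmap
}

#' Implied policy of a value map
#'
#' For every open cell, the arrow towards the accessible successor cell with
#' the maximum median value; rewarded cells map to `collect`. Cells whose
#' best successors are tied (within `tol`) are flagged.
#'
#' @param vmap Numeric value vector over states.
#' @param world The `gridworld` (defaults to the map attached to `vmap`).
#' @param tol Tie tolerance.
#' @return A data frame with columns `state`, `action` (action code, NA where
#'   no action), `tie`.
#' @export
implied_policy <- function(vmap, world = attr(vmap, "world"), tol = 1e-9) {
  stopifnot(inherits(world, "gridworld"))
  S <- world$n_states
  action <- rep(NA_integer_, S)
  tie <- rep(FALSE, S)
  for (s in seq_len(S)) {
    if (!world$open[s]) next
    if (world$terminal[s]) {
      action[s] <- ACTIONS[["collect"]]
      next
    }
    acts <- available_actions(world, s)
    acts <- acts[acts <= 4L]
    if (length(acts) == 0L) next
    vals <- vmap[world$neighbors[s, acts]]
    best <- which(vals >= max(vals) - tol)
    action[s] <- acts[best[1]]
    tie[s] <- length(best) > 1L
  }
  data.frame(state = seq_len(S), action = action, tie = tie)
}

#' Optimality verdict for an implied policy
#'
#' `"pass"` iff greedily following the policy from `start` reaches the cell
#' holding the maximal reward in exactly the shortest-path number of steps,
#' without crossing any tie-flagged cell. Entering a cycle, a lesser reward,
#' a tie, or overrunning the optimal step count all yield `"fail"`.
#'
#' @param pmap Policy data frame from [implied_policy()].
#' @param world The `gridworld`.
#' @param start Start cell reference.
#' @return `"pass"` or `"fail"`.
#' @export
policy_optimal <- function(pmap, world, start) {
  s <- state_index(world, start)
  rewarded <- which(world$open & world$rewards > 0)
  if (length(rewarded) == 0L) stop("world has no rewarded cell")
  goal <- rewarded[which.max(world$rewards[rewarded])]
  d_opt <- shortest_path_distances(world, goal)[s]
  if (!is.finite(d_opt)) stop("goal unreachable from start")
  steps <- 0
  visited <- logical(world$n_states)
  while (TRUE) {
    if (s == goal) return(if (steps == d_opt) "pass" else "fail")
    if (visited[s]) return("fail")                    # cycle
    visited[s] <- TRUE
    if (pmap$tie[s]) return("fail")                   # ambiguous choice
    a <- pmap$action[s]
    if (is.na(a) || a == ACTIONS[["collect"]]) return("fail")  # lesser reward
    s <- world$neighbors[s, a]
    steps <- steps + 1
    if (steps > d_opt) return("fail")
  }
}

#' Value iteration: the full model-based oracle
#'
#' Fixed point of the Bellman optimality recursion over the true available
#' actions: `V(s) = max_a [R(s, a) + gamma V(s')]`, with `collect` yielding
#' the cell's reward followed by the zero-valued terminal state.
#'
#' @param world A `gridworld`.
#' @param gamma Discount.
#' @param tol Convergence tolerance on the sup-norm of the update.
#' @return A list with `V` (optimal values, NA on walls) and `policy` (a data
#'   frame as from [implied_policy()] computed from `V`).
#' @export
value_iteration <- function(world, gamma = 0.95, tol = 1e-10) {
  S <- world$n_states
  V <- numeric(S)
  repeat {
    Vn <- numeric(S)
    for (s in seq_len(S)) {
      if (!world$open[s]) next
      acts <- available_actions(world, s)
      if (length(acts) == 0L) next
      q <- vapply(acts, function(a) {
        if (a == ACTIONS[["collect"]]) world$rewards[s]
        else gamma * V[world$neighbors[s, a]]
      }, 0)
      Vn[s] <- max(q)
    }
    if (max(abs(Vn - V)) < tol) break
    V <- Vn
  }
  V[!world$open] <- NA_real_
  list(V = V, policy = implied_policy(V, world))
}

#' Per-state agreement between a policy and the oracle's greedy policy
#'
#' Compares the implied policy of a (median) value map with the
#' value-iteration greedy policy on every open, non-rewarded state at which
#' the oracle's choice is unique (untied); oracle-tied states carry no
#' behavioural prediction and are excluded.
#'
#' @param pmap Policy data frame for the agent.
#' @param world The `gridworld`.
#' @param oracle Optional result of [value_iteration()].
#' @return A list with `n_compared`, `n_agree`, and `agreement` (fraction).
#' @export
policy_agreement <- function(pmap, world, oracle = NULL) {
  if (is.null(oracle)) oracle <- value_iteration(world)
  opol <- oracle$policy
  keep <- world$open & !world$terminal & !opol$tie & !is.na(opol$action)
  agree <- pmap$action[keep] == opol$action[keep] & !pmap$tie[keep]
  list(n_compared = sum(keep), n_agree = sum(agree),
       agreement = mean(agree))
}

#' Default agent configurations for the flexibility analysis
#'
#' The seven standard configurations: the one-step-lookahead TD foil, SR-TD,
#' SR-MB, and the two Dyna agents each under sufficient (`k = 10000`) and
#' insufficient (`k = 10`) post-change replay.
#'
#' @param params Base [agent_params()] shared by all configurations.
#' @return Named list of `list(kind, params)` configurations.
#' @export
default_agent_configs <- function(params = agent_params()) {
  k_hi <- function(p) { p$k_post_change <- 10000L; p }
  k_lo <- function(p) { p$k_post_change <- 10L; p }
  list(
    onestep_td     = list(kind = "onestep_td", params = params),
    sr_td          = list(kind = "sr_td", params = params),
    sr_mb          = list(kind = "sr_mb", params = params),
    sr_dyna_k10000 = list(kind = "sr_dyna", params = k_hi(params)),
    sr_dyna_k10    = list(kind = "sr_dyna", params = k_lo(params)),
    dyna_q_k10000  = list(kind = "dyna_q", params = k_hi(params)),
    dyna_q_k10     = list(kind = "dyna_q", params = k_lo(params))
  )
}

.task_start <- function(task) {
  switch(task, latent = "S", detour = "S", policy_reval = "S1",
         stop("unknown task"))
}

#' Agent-by-task flexibility matrix
#'
#' Runs every configuration through every revaluation task, reduces each
#' result to its median value map and implied policy, and scores the policy
#' against the shortest path to the maximal reward. The entries are the
#' categorical `"pass"` / `"fail"` verdicts that summarize each
#' architecture's behavioural flexibility.
#'
#' @param configs Named list of `list(kind, params)` (default
#'   [default_agent_configs()]).
#' @param tasks Character vector of task names.
#' @param n_runs Runs per agent-task cell.
#' @param seed Master seed (each cell derives its own stream).
#' @param keep_results Keep the full `gridsr_result` objects as attribute
#'   `results` (needed for further analysis of the same runs).
#' @param ... Passed to the task functions (e.g. `explore_steps`).
#' @return Character matrix (configs x tasks) of verdicts, with the median
#'   value maps attached as attribute `vmaps`.
#' @export
flexibility_matrix <- function(configs = default_agent_configs(),
                               tasks = c("latent", "detour", "policy_reval"),
                               n_runs = 100L, seed = 1L,
                               keep_results = FALSE, ...) {
  out <- matrix(NA_character_, length(configs), length(tasks),
                dimnames = list(names(configs), tasks))
  vmaps <- list()
  results <- list()
  cell <- 0L
  for (ti in seq_along(tasks)) {
    for (ci in seq_along(configs)) {
      cell <- cell + 1L
      cfg <- configs[[ci]]
      res <- run_task(tasks[ti], kind = cfg$kind, n_runs = n_runs,
                      seed = seed + 7919L * cell, params = cfg$params, ...)
      vmap <- median_value_map(res)
      pmap <- implied_policy(vmap, res$world)
      out[ci, ti] <- policy_optimal(pmap, res$world, .task_start(tasks[ti]))
      vmaps[[paste(names(configs)[ci], tasks[ti], sep = ".")]] <- vmap
      if (keep_results) {
        results[[paste(names(configs)[ci], tasks[ti], sep = ".")]] <- res
      }
    }
  }
  attr(out, "vmaps") <- vmaps
  if (keep_results) attr(out, "results") <- results
  out
}

#' Parameter-robustness sweep
#'
#' Re-evaluates the flexibility verdicts across a lattice of parameter
#' settings, marking settings whose verdict differs from the
#' default-parameter verdict. The headline robustness property is
#' asymmetric: architectures that fail a task at the defaults fail it at
#' every lattice point, whereas architectures that pass at the defaults may
#' be made to fail at extreme settings.
#'
#' @param grid A data frame whose columns name [agent_params()] fields and
#'   whose rows are settings (e.g. `expand.grid(alpha_sr = c(.1, .3, .5))`).
#' @param configs,tasks,n_runs,seed,... As in [flexibility_matrix()].
#' @return A long data frame with columns `setting`, the grid columns,
#'   `config`, `task`, `verdict`, `differs_from_default`.
#' @export
parameter_sweep <- function(grid, configs = default_agent_configs(),
                            tasks = c("latent", "detour", "policy_reval"),
                            n_runs = 100L, seed = 1L, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  base <- flexibility_matrix(configs, tasks, n_runs, seed, ...)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfgs <- lapply(configs, function(cfg) {
      p <- cfg$params
      for (nm in names(grid)) p[[nm]] <- grid[[nm]][g]
      if (!is.null(p$weight_mode)) {
        p$weight_mode_code <- match(p$weight_mode,
                                    c("normalized", "plain", "direct")) - 1L
      }
      list(kind = cfg$kind, params = p)
    })
    fm <- flexibility_matrix(cfgs, tasks, n_runs, seed + 104729L * (g - 1L), ...)
    for (ci in seq_along(cfgs)) {
      for (ti in seq_along(tasks)) {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(setting = g), grid[g, , drop = FALSE],
          data.frame(config = names(configs)[ci], task = tasks[ti],
                     verdict = fm[ci, ti],
                     differs_from_default = fm[ci, ti] != base[ci, ti],
                     row.names = NULL))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a value map and implied policy as text
#'
#' A compact console display mirroring the figure panels: per-cell median
#' value (grayscale in the figures, numbers here) and the implied-policy
#' arrow.
#'
#' @param vmap Value map.
#' @param world The `gridworld`.
#' @return Invisibly, a character matrix of arrows.
#' @export
render_policy_text <- function(vmap, world = attr(vmap, "world")) {
  pmap <- implied_policy(vmap, world)
  glyphs <- c("^", ">", "v", "<", "$")
  out <- matrix(" ", world$height, world$width)
  for (s in seq_len(world$n_states)) {
    x <- world$coords[s, 1] + 1L; y <- world$coords[s, 2] + 1L
    if (!world$open[s]) { out[y, x] <- "#" ; next }
    a <- pmap$action[s]
    out[y, x] <- if (is.na(a)) "." else if (pmap$tie[s]) "?" else glyphs[a]
  }
  out[is.na(world$state_at)] <- "#"
  cat(apply(out, 1, paste, collapse = ""), sep = "\n")
  invisible(out)
}

#' Export a value map as CSV
#'
#' Writes per-cell rows `x, y, state, value` for open cells.
#'
#' @param vmap Value map.
#' @param path Output file.
#' @param world The `gridworld`.
#' @return Invisibly, `path`.
#' @export
write_value_map_csv <- function(vmap, path, world = attr(vmap, "world")) {
  open <- which(world$open)
  utils::write.csv(
    data.frame(x = world$coords[open, 1], y = world$coords[open, 2],
               state = open, value = vmap[open]),
    path, row.names = FALSE)
  invisible(path)
}
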