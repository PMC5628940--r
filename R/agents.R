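# The five agent architectures as stateful policies over a gridworld.
# Construction and the single-step / protocol execution are backed by the
# compiled engine; the exported helper operations below define the update
# arithmetic at the R level.

#' Agent parameters
#'
#' Defaults are the standard simulation settings: discount `gamma = 0.95`,
#' epsilon-greedy exploration `epsilon = 0.1`, weight and Q learning rates
#' `alpha_w = alpha_q = 0.3`, occupancy learning rate `alpha_sr = 0.3`, and
#' policy learning rate `alpha_pi = 0.1`. Dyna agents replay
#' `n_replay_per_step = 10` stored samples after every step and
#' `k_post_change` samples after any step on which a learned change to the
#' reward function or to the available actions occurred; `k_post_change` is
#' 10 in the insufficient-replay condition and 10000 in the sufficient-replay
#' condition.
#'
#' `weight_mode` selects how SR agents learn the reward weights:
#' `"normalized"` (TD with features scaled by their squared norm, the
#' default), `"plain"` (raw linear-TD gradient), or `"direct"` (delta rule on
#' the immediate reward, ignoring features). `replay_lambda` is the rate of
#' the exponential recency distribution over sample ranks (most recent =
#' rank 0). `change_tol` is the margin by which a realized reward must
#' deviate from the agent's current estimate for a collect transition to
#' count as a learned change in the reward function.
#'
#' @param gamma,epsilon,alpha_w,alpha_sr,alpha_q,alpha_pi Core learning
#'   parameters.
#' @param n_replay_per_step,k_post_change Replay budget per step and per
#'   detected change (Dyna agents only).
#' @param weight_mode Weight-learning rule for SR agents.
#' @param replay_lambda Exponential recency rate for replay sampling.
#' @param change_tol Reward change-detection margin.
#' @return A named list of class `agent_params`.
#' @export
agent_params <- function(gamma = 0.95, epsilon = 0.1, alpha_w = 0.3,
                         alpha_sr = 0.3, alpha_q = 0.3, alpha_pi = 0.1,
                         n_replay_per_step = 10L, k_post_change = 10L,
                         weight_mode = c("normalized", "plain", "direct"),
                         replay_lambda = 1 / 5, change_tol = 0.01) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(gamma >= 0, gamma < 1, epsilon >= 0, epsilon <= 1,
            alpha_w > 0, alpha_w <= 1, alpha_sr > 0, alpha_sr <= 1,
            alpha_q > 0, alpha_q <= 1, alpha_pi > 0, alpha_pi <= 1,
            n_replay_per_step >= 0, k_post_change >= 0)
  structure(list(gamma = gamma, epsilon = epsilon, alpha_w = alpha_w,
                 alpha_sr = alpha_sr, alpha_q = alpha_q, alpha_pi = alpha_pi,
                 n_replay_per_step = as.integer(n_replay_per_step),
                 k_post_change = as.integer(k_post_change),
                 weight_mode = weight_mode,
                 weight_mode_code = match(weight_mode,
                                          c("normalized", "plain", "direct")) - 1L,
                 replay_lambda = replay_lambda, change_tol = change_tol),
            class = "agent_params")
}

#' Agent architectures
#'
#' The available agent kinds:
#' \describe{
#'   \item{`onestep_td`}{TD learning of state values over a punctate state
#'     representation, with one step of model-based lookahead to convert `V`
#'     to `Q`. The model-free foil.}
#'   \item{`sr_td`}{The original successor representation: a TD-learned
#'     occupancy matrix `M` plus TD-learned reward weights `w`; `V = M w`.}
#'   \item{`sr_mb`}{Recomputes `M = (I - gamma T)^-1` before every choice
#'     from a learned one-step model: the deterministic grid physics, an
#'     observed per-state available-action set, and a delta-rule estimate of
#'     the agent's own past policy.}
#'   \item{`sr_dyna`}{A state-action successor matrix `H` learned on-policy
#'     online (SARSA-style) and updated off-policy by replaying stored
#'     samples with the currently best continuation action.}
#'   \item{`dyna_q`}{Classic Dyna-Q: tabular Q-learning plus replay of
#'     stored samples.}
#' }
#'
#' @param kind One of `"onestep_td"`, `"sr_td"`, `"sr_mb"`, `"sr_dyna"`,
#'   `"dyna_q"`.
#' @param world The `gridworld` the agent will act in (fixes matrix
#'   dimensions).
#' @param params An [agent_params()] list.
#' @return An object of class `gridsr_agent` holding the agent's internal
#'   structures (`$state`) and parameters.
#' @export
make_agent <- function(kind = c("onestep_td", "sr_td", "sr_mb", "sr_dyna",
                                "dyna_q"),
                       world, params = agent_params()) {
  kind <- match.arg(kind)
  stopifnot(inherits(world, "gridworld"), inherits(params, "agent_params"))
  structure(list(kind = kind, params = params,
                 n_states = world$n_states,
                 state = .agent_init_cpp(kind, world$n_states)),
            class = "gridsr_agent")
}

#' @export
print.gridsr_agent <- function(x, ...) {
  cat(sprintf("<%s agent over %d states>\n", x$kind, x$n_states))
  invisible(x)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the highest-valued action is chosen (ties
#' broken uniformly at random); with probability `epsilon` an action is drawn
#' uniformly from all available actions (including the greedy one).
#'
#' @param q_row Named numeric vector of action values for the available
#'   actions.
#' @param epsilon Exploration probability.
#' @return The selected element index into `q_row`.
#' @export
epsilon_greedy <- function(q_row, epsilon) {
  m <- length(q_row)
  if (m == 0L) stop("epsilon_greedy requires at least one available action")
  if (m == 1L) return(1L)
  if (stats::runif(1) < epsilon) return(sample.int(m, 1L))
  best <- which(q_row >= max(q_row) - 1e-9)
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' One-step lookahead action values from a state-value function
#'
#' `Q(s, a) = V(s')` where `s'` deterministically follows `a` in `s`;
#' `collect` maps to the terminal value 0. Omitting the immediate reward is
#' exact here because rewards are paired exclusively with the terminal
#' `collect` action.
#'
#' @param V State-value vector.
#' @param world A `gridworld`.
#' @param s State reference.
#' @return Named numeric vector over the available actions.
#' @export
onestep_lookahead_q <- function(V, world, s) {
  s <- state_index(world, s)
  acts <- available_actions(world, s)
  vapply(acts, function(a) {
    if (a == ACTIONS[["collect"]]) 0 else V[world$neighbors[s, a]]
  }, 0)
}

#' Delta-rule update of a cached policy row
#'
#' `pi(. | s) <- alpha_pi * onehot(a) + (1 - alpha_pi) * pi(. | s)`; the row
#' remains a probability distribution over the four cardinal action slots.
#'
#' @param pi_row Length-4 probability vector.
#' @param chosen Cardinal action code (1..4).
#' @param alpha_pi Policy learning rate.
#' @return Updated probability row.
#' @export
srmb_policy_update <- function(pi_row, chosen, alpha_pi) {
  chosen <- as.integer(chosen)
  stopifnot(length(pi_row) == 4L, chosen >= 1L, chosen <= 4L)
  onehot <- numeric(4)
  onehot[chosen] <- 1
  alpha_pi * onehot + (1 - alpha_pi) * pi_row
}

#' Model-computed transition row from policy and believed availability
#'
#' `T(s, .) = sum_{a in A_s} pi(a | s) onehot(succ(s, a)) / sum_{a in A_s}
#' pi(a | s)`: the cached policy renormalized over the believed-available
#' actions, pushed through the deterministic grid physics. A state believed
#' to offer only `collect` produces an all-zero row (its mass exits to the
#' terminal state).
#'
#' @param pi_row Length-4 cardinal policy row.
#' @param avail Believed-available action codes at `s` (subset of 1..5).
#' @param successors Length-4 vector of successor state indices for the
#'   cardinal actions (0 where the move is physically impossible).
#' @param n_states Row length.
#' @return Numeric transition row of length `n_states`.
#' @export
srmb_transition_row <- function(pi_row, avail, successors, n_states) {
  row <- numeric(n_states)
  cardinal <- avail[avail <= 4L]
  if (length(cardinal) == 0L) return(row)
  total <- sum(pi_row[cardinal])
  if (total <= 0) stop("policy places no mass on believed-available actions")
  for (a in cardinal) {
    dest <- successors[a]
    if (dest == 0L) next
    row[dest] <- row[dest] + pi_row[a] / total
  }
  row
}

#' Q-learning update from a sample
#'
#' `Q(s, a) <- Q(s, a) + alpha_q * (r + gamma * max_{a'} Q(s', a') -
#' Q(s, a))`, maximizing over the actions available at `s'`; the terminal
#' continuation is 0. Only the `(s, a)` entry changes.
#'
#' @param Q `n_states x 5` action-value matrix.
#' @param s,a,r,s_next The sample (`s_next = NA` for terminal).
#' @param alpha_q Learning rate.
#' @param gamma Discount.
#' @param avail_next Available action codes at `s_next` (ignored when
#'   terminal).
#' @return The updated matrix.
#' @export
dynaq_update <- function(Q, s, a, r, s_next, alpha_q, gamma,
                         avail_next = NULL) {
  cont <- if (is.na(s_next)) 0 else {
    if (is.null(avail_next) || length(avail_next) == 0L) 0
    else max(Q[s_next, avail_next])
  }
  Q[s, a] <- Q[s, a] + alpha_q * (r + gamma * cont - Q[s, a])
  Q
}

#' Draw replay samples from an experience buffer
#'
#' Two schemes, both with replacement and both using an exponential recency
#' distribution over sample ranks, `P(rank j) ~ exp(-lambda j)` with the most
#' recent sample at rank 0:
#' \describe{
#'   \item{`per_step`}{the rank distribution is applied to the whole buffer
#'     (the recency-weighted bias used between decisions);}
#'   \item{`post_change`}{a state-action pair is first drawn uniformly from
#'     the pairs present in the buffer, then the rank distribution is applied
#'     within that pair's samples.}
#' }
#'
#' @param buffer A data frame with columns `s`, `a` (and any others), ordered
#'   oldest to newest.
#' @param count Number of draws.
#' @param scheme `"per_step"` or `"post_change"`.
#' @param lambda Recency rate.
#' @return Integer vector of row indices into `buffer` (empty, with a
#'   warning, if the buffer is empty).
#' @export
draw_replay_samples <- function(buffer, count,
                                scheme = c("per_step", "post_change"),
                                lambda = 1 / 5) {
  scheme <- match.arg(scheme)
  n <- nrow(buffer)
  if (is.null(n) || n == 0L) {
    warning("empty replay buffer")
    return(integer(0))
  }
  draw_rank <- function(nn) {
    q <- exp(-lambda)
    u <- stats::runif(1)
    j <- floor(log(1 - u * (1 - q^nn)) / log(q))
    min(max(j, 0), nn - 1)
  }
  if (scheme == "per_step") {
    vapply(seq_len(count), function(i) as.integer(n - draw_rank(n)), 0L)
  } else {
    sa <- paste(buffer$s, buffer$a)
    by_sa <- split(seq_len(n), sa)
    vapply(seq_len(count), function(i) {
      lst <- by_sa[[sample.int(length(by_sa), 1L)]]
      as.integer(lst[length(lst) - draw_rank(length(lst))])
    }, 0L)
  }
}

#' Advance an agent by one environment step
#'
#' Chooses an action by epsilon-greedy over the agent's action values at
#' `s`, applies the environment transition, and runs the agent's own
#' learning updates (including any replay for Dyna agents). All randomness
#' is drawn from R's global generator; seed with [set.seed()] for
#' reproducible runs.
#'
#' @param agent A `gridsr_agent`.
#' @param world The `gridworld`.
#' @param s State reference for the agent's current position.
#' @return A list with the updated `agent` and the realized `transition`
#'   (`s`, `action`, `reward`, `s_next`, `terminal`).
#' @export
agent_step <- function(agent, world, s) {
  s <- state_index(world, s)
  if (!world$open[s]) stop("agent cannot occupy a walled cell")
  res <- .run_protocol_cpp(agent$kind, agent$state, agent$params,
                           list(list(type = "world",
                                     world = .world_compiled(world)),
                                list(type = "step", at = s)))
  agent$state <- res$state
  list(agent = agent,
       transition = list(s = s, action = res$last_action,
                         reward = res$last_reward,
                         s_next = res$last_s_next,
                         terminal = is.na(res$last_s_next)))
}

#' Current value table of an agent
#'
#' For value-based agents (`onestep_td`, `sr_td`, `sr_mb`) this is the state
#' value function `V`; for Q-based agents (`sr_dyna`, `dyna_q`) the maximum
#' action value available in each state. Walled cells are `NA`.
#'
#' @param agent A `gridsr_agent`.
#' @param world The `gridworld`.
#' @return Numeric vector of length `n_states`.
#' @export
agent_values <- function(agent, world) {
  res <- .run_protocol_cpp(agent$kind, agent$state, agent$params,
                           list(list(type = "world",
                                     world = .world_compiled(world)),
                                list(type = "record")))
  res$values[[1]]
}

#' Let an agent behave freely for a number of steps
#'
#' Runs the agent's epsilon-greedy behaviour and learning updates for
#' `steps` environment steps starting from `start`, teleporting back to
#' `start` whenever a terminal reward site is entered. In a rewardless world
#' all action values stay tied, so behaviour reduces to a uniform random
#' walk -- the exploration regime of the revaluation protocols.
#'
#' @param agent A `gridsr_agent`.
#' @param world The `gridworld`.
#' @param steps Number of environment steps.
#' @param start Start cell reference.
#' @return The updated agent.
#' @export
agent_explore <- function(agent, world, steps, start) {
  res <- .run_protocol_cpp(agent$kind, agent$state, agent$params,
                           list(list(type = "world",
                                     world = .world_compiled(world)),
                                list(type = "explore",
                                     steps = as.integer(steps),
                                     start = state_index(world, start))))
  agent$state <- res$state
  agent
}

#' Extract an agent's successor matrix
#'
#' Returns the occupancy matrix in conventional orientation (rows = source
#' states): `M` for `sr_td`, `H` for `sr_dyna`. For `sr_mb` the matrix is
#' recomputed from the agent's current one-step model, which requires the
#' `world`.
#'
#' @param agent A `gridsr_agent`.
#' @param world Required for `sr_mb` only.
#' @return A numeric matrix.
#' @export
agent_successor_matrix <- function(agent, world = NULL) {
  switch(agent$kind,
    sr_td = t(agent$state$MT),
    sr_dyna = t(agent$state$HT),
    sr_mb = {
      if (is.null(world)) stop("sr_mb needs the world to rebuild its model")
      S <- agent$n_states
      Tm <- matrix(0, S, S)
      for (s in seq_len(S)) {
        bm <- agent$state$Abelief[s]
        if (bm == 0L || bitwAnd(bm, 16L) > 0L) next
        acts <- which(bitwAnd(bm, bitwShiftL(1L, 0:3)) > 0L)
        Tm[s, ] <- srmb_transition_row(agent$state$pi[s, ], acts,
                                       ifelse(world$neighbors[s, ] > 0L,
                                              world$neighbors[s, ], s), S)
      }
      solve(diag(S) - agent$params$gamma * Tm)
    },
    stop(sprintf("agent kind '%s' has no successor matrix", agent$kind)))
}
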