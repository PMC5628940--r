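# Successor-representation mathematics: occupancy matrices over states (M)
# and state-actions (H), their TD / closed-form / replay updates, and linear
# value decoding. These reference implementations define the update rules;
# the C++ protocol engine applies the same arithmetic in its inner loops.

#' Temporal-difference reward prediction error
#'
#' `delta = r + gamma * v_next - v_cur`. Pass `v_next = 0` when the successor
#' is the absorbing terminal state.
#'
#' @param r Immediate reward.
#' @param gamma Discount factor in `[0, 1)`.
#' @param v_next Value of the successor state (0 at terminal).
#' @param v_cur Value of the current state.
#' @return The scalar prediction error.
#' @export
td_error <- function(r, gamma, v_next, v_cur) {
  r + gamma * v_next - v_cur
}

#' TD update of a successor-matrix row
#'
#' After a transition `s -> s_next`, row `s` of the occupancy matrix moves
#' towards the one-sample estimate `onehot(s) + gamma * M[s_next, ]`:
#' `M[s, ] <- M[s, ] + alpha_sr * (onehot(s) + gamma * M[s_next, ] - M[s, ])`.
#' The terminal continuation is the zero vector (`s_next = NA`). Only row `s`
#' changes.
#'
#' @param M Square occupancy matrix (states x states).
#' @param s Current state index (nonterminal).
#' @param s_next Successor state index, or `NA` for terminal.
#' @param alpha_sr Occupancy learning rate.
#' @param gamma Discount factor.
#' @return The updated matrix.
#' @export
sr_td_update <- function(M, s, s_next, alpha_sr, gamma) {
  if (is.na(s) || s < 1L || s > nrow(M)) stop("s must be a valid nonterminal state")
  target <- numeric(ncol(M))
  target[s] <- 1
  if (!is.na(s_next)) target <- target + gamma * M[s_next, ]
  M[s, ] <- M[s, ] + alpha_sr * (target - M[s, ])
  M
}

#' TD update of the linear reward weights
#'
#' Linear-function-approximation TD: `w <- w + alpha_w * delta * f` with
#' feature vector `f` (a row of the occupancy matrix). In `"normalized"` mode
#' the features are divided by their squared norm, `f / (f . f)`, so that
#' `alpha_w` keeps its interpretation as a proportional step size regardless
#' of the feature scale (normalized least-mean-squares); `"plain"` mode
#' applies the raw gradient step and is retained for sensitivity checks.
#'
#' @param w Weight vector.
#' @param features Feature vector (occupancy row), same length as `w`.
#' @param delta TD error.
#' @param alpha_w Weight learning rate.
#' @param mode `"normalized"` (default) or `"plain"`.
#' @return The updated weight vector. All-zero features in normalized mode
#'   skip the update with a warning.
#' @export
weight_update_td <- function(w, features, delta, alpha_w,
                             mode = c("normalized", "plain")) {
  mode <- match.arg(mode)
  if (length(features) != length(w)) stop("feature/weight length mismatch")
  if (mode == "normalized") {
    nrm2 <- sum(features^2)
    if (nrm2 == 0) {
      warning("all-zero features: skipping normalized weight update")
      return(w)
    }
    features <- features / nrm2
  }
  w + alpha_w * delta * features
}

#' Delta-rule learning of one-step rewards
#'
#' Direct reward learning: `w[s] <- w[s] + alpha_w * (r - w[s])`. Used as the
#' comparison weight-learning mode in acquisition experiments; unlike the TD
#' rule it ignores the occupancy features entirely.
#'
#' @param w Weight vector.
#' @param s State index.
#' @param r Observed immediate reward.
#' @param alpha_w Learning rate.
#' @return The updated weight vector.
#' @export
weight_update_direct <- function(w, s, r, alpha_w) {
  w[s] <- w[s] + alpha_w * (r - w[s])
  w
}

#' Decode state values from an occupancy matrix
#'
#' `V = M %*% w`: the value of a state is its expected discounted future
#' occupancy of every state, weighted by each state's one-step reward.
#'
#' @param M Occupancy matrix.
#' @param w Weight vector.
#' @return Numeric value vector.
#' @export
value_from_sr <- function(M, w) {
  if (ncol(M) != length(w)) stop("dimension mismatch between M and w")
  as.numeric(M %*% w)
}

#' One-step transition matrix of a policy on a gridworld
#'
#' `T[s, s'] = sum_a pi(a | s) P(s' | s, a)` over the available cardinal
#' actions. Rows of reward sites (whose only action is `collect`) and of
#' walled cells are all zero: their probability mass exits to the absorbing
#' terminal state. With `policy = NULL` the uniform random policy over
#' available actions is used.
#'
#' @param world A `gridworld`.
#' @param policy Optional `n_states x 4` matrix of cardinal-action
#'   probabilities; each row is renormalized over the actions available in
#'   that state.
#' @return An `n_states x n_states` (sub)stochastic matrix.
#' @export
transition_matrix <- function(world, policy = NULL) {
  S <- world$n_states
  Tm <- matrix(0, S, S)
  for (s in seq_len(S)) {
    if (!world$open[s] || world$terminal[s]) next
    acts <- available_actions(world, s)
    acts <- acts[acts <= 4L]
    if (length(acts) == 0L) next
    p <- if (is.null(policy)) rep(1, length(acts)) else policy[s, acts]
    if (sum(p) <= 0) stop(sprintf("policy has no mass on available actions in state %d", s))
    p <- p / sum(p)
    for (i in seq_along(acts)) {
      Tm[s, world$neighbors[s, acts[i]]] <-
        Tm[s, world$neighbors[s, acts[i]]] + p[i]
    }
  }
  Tm
}

#' Closed-form successor matrix from a transition matrix
#'
#' Either the matrix-inversion solution `M = (I - gamma T)^-1` or the
#' truncated Neumann series `sum_{n=0}^{N} gamma^n T^n`. For a substochastic
#' `T` and `gamma < 1` both exist and agree; the default series length
#' `n_terms = 500` leaves a truncation error below `gamma^500`, far under
#' double-precision test tolerances at `gamma = 0.95`.
#'
#' @param Tm Square (sub)stochastic one-step transition matrix.
#' @param gamma Discount factor in `[0, 1)`.
#' @param method `"inversion"` or `"series"`.
#' @param n_terms Series truncation length.
#' @return The successor (discounted occupancy) matrix.
#' @export
successor_from_transition <- function(Tm, gamma,
                                      method = c("inversion", "series"),
                                      n_terms = 500L) {
  method <- match.arg(method)
  S <- nrow(Tm)
  if (method == "inversion") {
    M <- solve(diag(S) - gamma * Tm)
  } else {
    M <- diag(S)
    P <- diag(S)
    for (n in seq_len(n_terms)) {
      P <- gamma * (P %*% Tm)
      M <- M + P
      if (max(abs(P)) < 1e-300) break
    }
  }
  M
}

#' State-action pair index
#'
#' State-action pairs are laid out state-major: `sa = (s - 1) * 5 + a` with
#' the action order of [ACTIONS]. All five action slots exist for every state
#' from the start, so that introducing a reward mid-run (which swaps a cell's
#' action set to `collect`) never resizes the matrices; never-available pairs
#' simply keep their initialization.
#'
#' @param s State index.
#' @param a Action code.
#' @return Integer pair index into an `H` matrix.
#' @export
sa_index <- function(s, a) {
  (as.integer(s) - 1L) * 5L + as.integer(a)
}

#' On-policy TD update of the state-action successor matrix
#'
#' After performing `sa` and then `sa_next`, row `sa` of `H` moves towards
#' `onehot(sa) + gamma * H[sa_next, ]`; the terminal continuation
#' (`sa_next = NA`) is the zero vector.
#'
#' @param H `(5 S) x (5 S)` state-action occupancy matrix.
#' @param sa Current pair index.
#' @param sa_next Next pair index or `NA` for terminal.
#' @param alpha_sr Learning rate.
#' @param gamma Discount factor.
#' @return The updated matrix.
#' @export
h_online_update <- function(H, sa, sa_next, alpha_sr, gamma) {
  target <- numeric(ncol(H))
  target[sa] <- 1
  if (!is.na(sa_next)) target <- target + gamma * H[sa_next, ]
  H[sa, ] <- H[sa, ] + alpha_sr * (target - H[sa, ])
  H
}

#' Off-policy replay update of the state-action successor matrix
#'
#' Replays a stored sample `(s, a, s_next)`. The continuation action is not
#' the one that was actually taken next but the best currently available one:
#' `a* = argmax_{a'} sum H[s_next a', ] * w`, with ties broken uniformly at
#' random. Row `sa` then moves towards `onehot(sa) + gamma * H[s_next a*, ]`;
#' a terminal sample (`s_next = NA`) contributes no continuation.
#'
#' @param H State-action occupancy matrix.
#' @param w State-action weight vector.
#' @param s,a,s_next The replayed sample (`s_next = NA` when terminal).
#' @param world The `gridworld` supplying the available actions at `s_next`.
#' @param alpha_sr Learning rate.
#' @param gamma Discount factor.
#' @return The updated matrix.
#' @export
h_offpolicy_replay_update <- function(H, w, s, a, s_next, world,
                                      alpha_sr, gamma) {
  sa <- sa_index(s, a)
  target <- numeric(ncol(H))
  target[sa] <- 1
  if (!is.na(s_next)) {
    acts <- available_actions(world, s_next)
    if (length(acts) == 0L) stop("no available action at replayed successor")
    q <- vapply(acts, function(ac) sum(H[sa_index(s_next, ac), ] * w), 0)
    best <- acts[q >= max(q) - 1e-12]
    a_star <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    target <- target + gamma * H[sa_index(s_next, a_star), ]
  }
  H[sa, ] <- H[sa, ] + alpha_sr * (target - H[sa, ])
  H
}

#' Decode state-action values from H
#'
#' `Q = H %*% w` over state-action pairs.
#'
#' @param H State-action occupancy matrix.
#' @param w State-action weight vector.
#' @return Numeric vector of Q values, one per pair index.
#' @export
q_from_h <- function(H, w) {
  if (ncol(H) != length(w)) stop("dimension mismatch between H and w")
  as.numeric(H %*% w)
}

#' Export a labelled occupancy matrix as CSV
#'
#' Writes a dense matrix with state (or state-action) labels as header row
#' and first column.
#'
#' @param M Matrix to write.
#' @param path Output file.
#' @param labels Optional row/column labels; defaults to `s1, s2, ...`.
#' @return Invisibly, `path`.
#' @export
write_matrix_csv <- function(M, path, labels = NULL) {
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(M)))
  out <- cbind(state = labels, as.data.frame(M))
  names(out) <- c("state", labels)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
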