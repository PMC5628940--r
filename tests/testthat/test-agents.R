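test_that("epsilon-greedy selection matches its closed-form probabilities", {
  expect_equal(epsilon_greedy(c(x = 1), 0.1), 1L)

  set.seed(42)
  # distinct maximum among 4 actions: P(best) = 0.9 + 0.1/4 = 0.925
  n <- 1e5
  picks <- vapply(seq_len(n), function(i) epsilon_greedy(c(0, 1, 2, 5), 0.1), 0L)
  p_hat <- mean(picks == 4L)
  se3 <- 3 * sqrt(0.925 * 0.075 / n)
  expect_lt(abs(p_hat - 0.925), se3)

  # full tie: uniform over available actions
  picks <- vapply(seq_len(2e4), function(i) epsilon_greedy(numeric(4), 0.1), 0L)
  expect_lt(max(abs(tabulate(picks, 4) / 2e4 - 0.25)), 3 * sqrt(0.25 * 0.75 / 2e4))

  expect_error(epsilon_greedy(numeric(0), 0.1), "at least one")
})

test_that("one-step lookahead copies successor values through", {
  g <- open_grid(3, 3)
  centre <- state_index(g, c(1, 1))
  V <- numeric(g$n_states)
  expect_equal(unname(onestep_lookahead_q(V, g, centre)), rep(0, 4))
  V[g$neighbors[centre, ]] <- c(1, 3, 0, 0)
  expect_equal(unname(onestep_lookahead_q(V, g, centre)), c(1, 3, 0, 0))
  # collect maps to the terminal value 0
  w <- set_reward(corridor_world(3), "R1", 10)
  expect_equal(unname(onestep_lookahead_q(rep(5, 3), w, "R1")), 0)
})

test_that("the cached-policy delta rule keeps rows stochastic", {
  row <- rep(0.25, 4)
  r1 <- srmb_policy_update(row, 1L, 0.1)
  expect_equal(r1, c(0.325, 0.225, 0.225, 0.225))
  expect_equal(sum(r1), 1)
  expect_equal(srmb_policy_update(row, 3L, 1), c(0, 0, 1, 0))
  for (i in 1:50) row <- srmb_policy_update(row, 2L, 0.1)
  expect_gt(row[2], 0.99)
})

test_that("model-computed transition rows renormalize over believed actions", {
  succ <- c(2L, 3L, 4L, 5L)
  r <- srmb_transition_row(rep(0.25, 4), avail = 1:4, successors = succ, 6L)
  expect_equal(r[2:5], rep(0.25, 4))
  # dropping a blocked action renormalizes to 1/3
  r2 <- srmb_transition_row(rep(0.25, 4), avail = c(1L, 3L, 4L), succ, 6L)
  expect_equal(r2[c(2, 4, 5)], rep(1 / 3, 3))
  expect_equal(sum(r2), 1)
  # believed collect-only: all mass exits to the terminal state
  expect_equal(srmb_transition_row(rep(0.25, 4), avail = 5L, succ, 6L),
               numeric(6))
})

test_that("the Q-learning update is local and uses the available-action max", {
  Q <- matrix(0, 3, 5)
  Q2 <- dynaq_update(Q, s = 3L, a = 5L, r = 10, s_next = NA,
                     alpha_q = 0.3, gamma = 0.95)
  expect_equal(Q2[3, 5], 3)
  expect_equal(sum(Q2 != 0), 1L)
  # consistent value: no change
  Qc <- Q; Qc[1, 2] <- 0.95 * 5; Qc[2, 1] <- 5
  expect_equal(dynaq_update(Qc, 1L, 2L, 0, 2L, 0.3, 0.95, avail_next = 1L), Qc)
  # repeated sweeps over a 2-state chain's samples reach gamma-discounted values
  Q <- matrix(0, 2, 5)
  for (i in 1:300) {
    Q <- dynaq_update(Q, 2L, 5L, 10, NA, 0.3, 0.95)
    Q <- dynaq_update(Q, 1L, 2L, 0, 2L, 0.3, 0.95, avail_next = 5L)
  }
  expect_equal(Q[2, 5], 10, tolerance = 1e-6)
  expect_equal(Q[1, 2], 9.5, tolerance = 1e-6)
})

test_that("replay draws respect the recency law and pair uniformity", {
  buf <- data.frame(s = c(1, 1), a = c(2, 2))
  set.seed(7)
  idx <- draw_replay_samples(buf, 1e5, scheme = "post_change", lambda = 1 / 5)
  p_recent <- mean(idx == 2L)
  p_exp <- exp(1 / 5) / (1 + exp(1 / 5))  # ratio e^(1/5) between ranks
  expect_lt(abs(p_recent - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))

  # uniform first stage: pairs equally likely regardless of sample counts
  buf2 <- data.frame(s = c(1, 1, 1, 1, 1, 2), a = c(1, 1, 1, 1, 1, 1))
  idx2 <- draw_replay_samples(buf2, 2e4, scheme = "post_change")
  p_sa2 <- mean(idx2 == 6L)
  expect_lt(abs(p_sa2 - 0.5), 3 * sqrt(0.25 / 2e4))

  buf1 <- data.frame(s = 1, a = 1)
  expect_equal(draw_replay_samples(buf1, 3), rep(1L, 3))
  expect_warning(out <- draw_replay_samples(data.frame(), 3), "empty")
  expect_length(out, 0L)
})

test_that("single agent steps apply each architecture's update rule", {
  # forced corridor: S -> open cell, no choice randomness
  w <- parse_grid_map("S.")
  set.seed(1)
  ag <- make_agent("sr_td", w)
  st <- agent_step(ag, w, "S")
  expect_equal(st$transition$action, unname(ACTIONS[["E"]]))
  M_ref <- sr_td_update(diag(2), 1L, 2L, 0.3, 0.95)
  expect_equal(matrix(t(st$agent$state$MT), 2), M_ref)
  expect_equal(st$agent$state$w, numeric(2))  # no reward signal yet

  # collect probe: punctate feature gives w(R1) = alpha_w * delta = 3
  # (replay disabled so Dyna agents show the bare one-update arithmetic)
  wr <- set_reward(corridor_world(3), "R1", 10)
  p0 <- agent_params(n_replay_per_step = 0L, k_post_change = 0L)
  for (kind in c("sr_td", "sr_mb", "sr_dyna", "dyna_q", "onestep_td")) {
    set.seed(2)
    ag <- make_agent(kind, wr, p0)
    st <- agent_step(ag, wr, "R1")
    expect_true(st$transition$terminal)
    expect_equal(st$transition$reward, 10)
    vals <- agent_values(st$agent, wr)
    expect_equal(vals[state_index(wr, "R1")], 3,
                 tolerance = 1e-12, label = kind)
  }
})

test_that("with replay disabled a first collect touches only the local entry", {
  wr <- set_reward(corridor_world(4), "R1", 10)
  p <- agent_params(n_replay_per_step = 0L, k_post_change = 0L)
  set.seed(3)
  ag <- make_agent("dyna_q", wr, p)
  st <- agent_step(ag, wr, "R1")
  Q <- st$agent$state$Q
  expect_equal(Q[state_index(wr, "R1"), 5], 3)
  Q[state_index(wr, "R1"), 5] <- 0
  expect_true(all(Q == 0))
})

test_that("runs are reproducible from their seed", {
  w <- set_reward(task_map("acquisition"), "R1", 10)
  walk <- function(seed, kind) {
    set.seed(seed)
    ag <- make_agent(kind, w)
    s <- state_index(w, "S")
    for (i in 1:200) {
      st <- agent_step(ag, w, s)
      ag <- st$agent
      s <- if (st$transition$terminal) state_index(w, "S") else st$transition$s_next
    }
    agent_values(ag, w)
  }
  for (kind in c("sr_td", "sr_dyna", "dyna_q")) {
    expect_identical(walk(11, kind), walk(11, kind))
  }
  expect_false(identical(walk(11, "sr_dyna"), walk(12, "sr_dyna")))
})
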