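test_that("td_error is the plain reward-prediction error", {
  expect_equal(td_error(0, 0.95, 0, 0), 0)
  expect_equal(td_error(10, 0.95, 0, 0), 10)
  # fixed point: v_cur = r + gamma v_next
  expect_equal(td_error(0, 0.95, 4, 0.95 * 4), 0)
})

test_that("sr_td_update moves one row towards the one-sample target", {
  M <- diag(3)
  M2 <- sr_td_update(M, 1L, 2L, alpha_sr = 0.3, gamma = 0.95)
  expect_equal(M2[1, ], c(1, 0.285, 0))
  expect_identical(M2[2:3, ], M[2:3, ])  # other rows untouched

  # collect transition from a converged punctate row is a fixed point
  M3 <- sr_td_update(diag(3), 2L, NA, alpha_sr = 0.3, gamma = 0.95)
  expect_equal(M3, diag(3))

  expect_error(sr_td_update(diag(3), NA, 1L, 0.3, 0.95), "nonterminal")
})

test_that("repeated chain updates converge to the geometric-series solution", {
  # deterministic chain s1 -> s2 -> terminal
  Tm <- matrix(0, 2, 2); Tm[1, 2] <- 1
  M_exact <- successor_from_transition(Tm, 0.95)
  M <- diag(2)
  for (i in 1:5000) {
    M <- sr_td_update(M, 1L, 2L, 0.01, 0.95)
    M <- sr_td_update(M, 2L, NA, 0.01, 0.95)
  }
  expect_equal(M, M_exact, tolerance = 1e-6)
  expect_equal(M[1, ], c(1, 0.95), tolerance = 1e-6)
})

test_that("weight updates follow the stated arithmetic", {
  w <- numeric(3)
  f <- c(0, 0, 1)  # punctate feature: normalized and plain coincide
  expect_equal(weight_update_td(w, f, delta = 10, alpha_w = 0.3),
               c(0, 0, 3))
  expect_equal(weight_update_td(w, f, 10, 0.3, mode = "plain"),
               c(0, 0, 3))
  # normalized mode rescales by the squared norm
  expect_equal(weight_update_td(numeric(2), c(2, 0), 1, 0.5),
               c(0.25, 0))
  expect_warning(w0 <- weight_update_td(w, numeric(3), 1, 0.3), "all-zero")
  expect_equal(w0, w)

  # 20 probe collects with delta recomputed each time: geometric approach
  w <- numeric(1)
  for (i in 1:20) {
    delta <- td_error(10, 0.95, 0, w[1])
    w <- weight_update_td(w, 1, delta, 0.3)
  }
  expect_equal(w[1], 10 * (1 - 0.7^20), tolerance = 1e-12)

  expect_equal(weight_update_direct(c(0, 0), 1L, 10, 0.3), c(3, 0))
  expect_equal(weight_update_direct(c(7, 0), 1L, 7, 0.3), c(7, 0))
  w <- 0
  for (i in 1:200) w <- weight_update_direct(w, 1L, 5, 0.3)
  expect_equal(w, 5, tolerance = 1e-12)
})

test_that("value decoding matches the linear model", {
  expect_equal(value_from_sr(diag(3), c(0, 10, 0)), c(0, 10, 0))
  M <- diag(3); M[1, 2] <- 0.95
  expect_equal(value_from_sr(M, c(0, 10, 0))[1], 9.5)
  expect_error(value_from_sr(diag(3), 1:2), "mismatch")
})

test_that("closed-form successor matrices: series, inversion, and chains", {
  expect_equal(successor_from_transition(matrix(0, 3, 3), 0.95), diag(3))

  # 2-state chain with an absorbing self-loop: row sums hit 1/(1-gamma)
  Tm <- matrix(c(0, 1, 0, 1), 2, 2, byrow = TRUE)
  M <- successor_from_transition(Tm, 0.95)
  expect_equal(M, matrix(c(1, 19, 0, 20), 2, 2, byrow = TRUE))

  # inversion and series agree on a random-policy grid
  g <- open_grid(4, 4)
  Tg <- transition_matrix(g)
  expect_lt(max(abs(successor_from_transition(Tg, 0.95, "inversion") -
                    successor_from_transition(Tg, 0.95, "series"))), 1e-6)
})

test_that("exact occupancies respect nonnegativity and the row-sum bound", {
  for (nm in c("latent", "detour", "policy_reval")) {
    w <- task_map(nm)
    M <- successor_from_transition(transition_matrix(w), 0.95)
    expect_true(all(M >= -1e-12))
    expect_true(all(rowSums(M) <= 1 / (1 - 0.95) + 1e-9))
    expect_true(all(diag(M)[!w$terminal] >= 1))
  }
})

test_that("policy evaluation via the SR equals the linear-system solution", {
  w <- set_reward(task_map("latent"), "R1", 10)
  Tm <- transition_matrix(w)
  rbar <- w$rewards  # one-step expected reward per state (collect only)
  M <- successor_from_transition(Tm, 0.95)
  V_sr <- value_from_sr(M, rbar)
  V_pe <- solve(diag(w$n_states) - 0.95 * Tm, rbar)
  expect_lt(max(abs(V_sr - V_pe)), 1e-6)
})

test_that("state-action occupancy updates mirror the state-level rules", {
  S <- 2L
  H <- diag(5 * S)
  sa1 <- sa_index(1, ACTIONS[["E"]])
  sa2 <- sa_index(2, ACTIONS[["collect"]])
  H2 <- h_online_update(H, sa1, sa2, 0.3, 0.95)
  expect_equal(H2[sa1, sa2], 0.285)
  expect_equal(H2[sa1, sa1], 1)
  # collect pair with a punctate row is a fixed point
  expect_equal(h_online_update(H, sa2, NA, 0.3, 0.95)[sa2, ], H[sa2, ])

  expect_equal(q_from_h(diag(4), c(1, 2, 3, 4)), c(1, 2, 3, 4))
})

test_that("off-policy replay follows the best available continuation", {
  w <- set_reward(corridor_world(3, reward = 10), "R1", 10)
  S <- w$n_states
  H <- diag(5 * S)
  wts <- numeric(5 * S)
  # state 2 offers E and W; make E (towards the reward) worth 5, W worth 3
  wts[sa_index(2, ACTIONS[["E"]])] <- 5
  wts[sa_index(2, ACTIONS[["W"]])] <- 3
  H2 <- h_offpolicy_replay_update(H, wts, s = 1L, a = ACTIONS[["E"]],
                                  s_next = 2L, world = w,
                                  alpha_sr = 0.3, gamma = 0.95)
  sa <- sa_index(1, ACTIONS[["E"]])
  expect_equal(H2[sa, sa_index(2, ACTIONS[["E"]])], 0.285)
  expect_equal(H2[sa, sa_index(2, ACTIONS[["W"]])], 0)

  # terminal sample: continuation is the zero vector
  H3 <- h_offpolicy_replay_update(H, wts, s = 3L, a = ACTIONS[["collect"]],
                                  s_next = NA, world = w,
                                  alpha_sr = 0.3, gamma = 0.95)
  expect_equal(H3[sa_index(3, 5), ], H[sa_index(3, 5), ])
})

test_that("matrix CSV export round-trips", {
  path <- tempfile(fileext = ".csv")
  write_matrix_csv(diag(2), path, labels = c("a", "b"))
  got <- utils::read.csv(path, check.names = FALSE)
  expect_equal(names(got), c("state", "a", "b"))
  expect_equal(got$a, c(1, 0))
})
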