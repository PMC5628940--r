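test_that("median value maps use the lower median and ignore run order", {
  res <- run_latent_learning("onestep_td", n_runs = 3, seed = 13,
                             explore_steps = 200)
  vm <- median_value_map(res)
  r1 <- state_index(res$world, "R1")
  per_run <- vapply(res$values, function(v) v[[1]][r1], 0)
  expect_equal(vm[r1], sort(per_run)[2])

  shuffled <- res
  shuffled$values <- res$values[c(3, 1, 2)]
  expect_equal(median_value_map(shuffled), vm)

  # even run count: the lower of the two central order statistics
  two <- res
  two$values <- res$values[1:2]
  expect_equal(median_value_map(two)[r1], min(per_run[1:2]))

  empty <- res
  empty$values <- list()
  empty$n_runs <- 0L
  expect_error(median_value_map(empty), "empty")
})

test_that("implied policies point up the value gradient", {
  w <- set_reward(corridor_world(5), "R1", 10)
  vmap <- c(1, 2, 3, 4, 10)
  pmap <- implied_policy(vmap, w)
  expect_equal(pmap$action[1:4], rep(unname(ACTIONS[["E"]]), 4))
  expect_equal(pmap$action[5], unname(ACTIONS[["collect"]]))
  expect_false(any(pmap$tie))

  # all-equal values tie every interior cell
  g <- open_grid(3, 3)
  pall <- implied_policy(numeric(9), g)
  expect_true(all(pall$tie))
})

test_that("policy optimality follows the shortest-path criterion", {
  w <- set_reward(corridor_world(5), "R1", 10)
  good <- implied_policy(c(1, 2, 3, 4, 10), w)
  expect_equal(policy_optimal(good, w, "S"), "pass")

  # a cycle never reaches the goal
  cyc <- good
  cyc$action[2] <- ACTIONS[["W"]]
  expect_equal(policy_optimal(cyc, w, "S"), "fail")

  # a tie on the trajectory is a fail
  tied <- good
  tied$tie[3] <- TRUE
  expect_equal(policy_optimal(tied, w, "S"), "fail")

  # leading to the smaller of two rewards is a fail
  w2 <- parse_grid_map("r...S....Q")
  w2 <- set_reward(w2, "R1", 10)
  w2 <- set_reward(w2, "R2", 20)
  vi <- value_iteration(w2)
  expect_equal(policy_optimal(vi$policy, w2, "S"), "pass")
  towards_small <- vi$policy
  towards_small$action[2:5] <- ACTIONS[["W"]]
  towards_small$tie[] <- FALSE
  expect_equal(policy_optimal(towards_small, w2, "S"), "fail")
})

test_that("value iteration reproduces closed-form optima", {
  w <- parse_grid_map("Sr")
  w <- set_reward(w, "R1", 10)
  vi <- value_iteration(w)
  expect_equal(vi$V[state_index(w, "R1")], 10)
  expect_equal(vi$V[state_index(w, "S")], 9.5)

  # two rewards: head towards the larger discounted return
  w2 <- set_reward(set_reward(parse_grid_map("r..S.....Q"), "R1", 10), "R2", 20)
  vi2 <- value_iteration(w2)
  s <- state_index(w2, "S")
  d1 <- shortest_path_distances(w2, "R1")[s]
  d2 <- shortest_path_distances(w2, "R2")[s]
  best <- if (0.95^d1 * 10 > 0.95^d2 * 20) "W" else "E"
  expect_equal(vi2$policy$action[s], unname(ACTIONS[[best]]))

  # no rewards anywhere: the optimal value function is identically zero
  g <- open_grid(3, 3)
  expect_equal(unname(value_iteration(g)$V), numeric(9))
})

test_that("the oracle's own greedy policy is optimal on every task map", {
  worlds <- list(
    latent = set_reward(task_map("latent"), "R1", 10),
    detour = insert_wall(set_reward(task_map("detour"), "R", 10), "B"),
    policy_reval = set_reward(set_reward(task_map("policy_reval"), "R1", 10),
                              "R2", 20))
  starts <- c(latent = "S", detour = "S", policy_reval = "S1")
  for (nm in names(worlds)) {
    vi <- value_iteration(worlds[[nm]])
    expect_equal(policy_optimal(vi$policy, worlds[[nm]], starts[[nm]]),
                 "pass", label = nm)
  }
})

test_that("policy agreement counts oracle-untied states only", {
  w <- set_reward(corridor_world(4), "R1", 10)
  vi <- value_iteration(w)
  agr <- policy_agreement(vi$policy, w, vi)
  expect_equal(agr$agreement, 1)
  expect_equal(agr$n_compared, 3L)
  wrong <- vi$policy
  wrong$action[1] <- ACTIONS[["W"]]
  expect_lt(policy_agreement(wrong, w, vi)$agreement, 1)
})

test_that("a single-point sweep reduces to the flexibility matrix", {
  cfg <- list(sr_td = list(kind = "sr_td", params = agent_params()))
  fm <- flexibility_matrix(cfg, tasks = "latent", n_runs = 3, seed = 31,
                           explore_steps = 400)
  sw <- parameter_sweep(data.frame(alpha_sr = 0.3), cfg, tasks = "latent",
                        n_runs = 3, seed = 31, explore_steps = 400)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$verdict, unname(fm[1, 1]))
  expect_false(sw$differs_from_default)
})

test_that("text rendering covers every open cell", {
  w <- set_reward(corridor_world(3), "R1", 10)
  out <- render_policy_text(c(1, 2, 10), w)
  expect_equal(dim(out), c(1L, 3L))
  expect_equal(out[1, 3], "$")
})
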