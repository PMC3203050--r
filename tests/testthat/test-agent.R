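test_that("value estimate is the weighted sum of activations", {
  expect_equal(value_estimate(numeric(3), c(1, 0, 0)), 0)
  expect_equal(value_estimate(c(1, 2), c(0.5, 0.5)), 1.5)
  b <- tabular_basis(4)
  w <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(value_estimate(w, b$Phi[3, ]), w[3])
  expect_error(value_estimate(1:2, 1:3), "mismatch")
})

test_that("single td_update closed forms", {
  b <- tabular_basis(4)
  # transition into a rewarded terminal state from zero weights: delta = 1
  cfg <- agent_config(alpha = 0.5, gamma = 0.9, lambda = 0)
  ag <- td_update(agent_state(4), cfg, b$Phi[2, ], r = 1, b$Phi[3, ],
                  terminal = TRUE)
  expect_equal(ag$delta, 1)
  expect_equal(ag$w, c(0, 0.5, 0, 0))
  # lambda = 0 reduces to one-step TD(0): trace equals the current one-hot
  expect_equal(ag$e, c(0, 1, 0, 0))
  expect_error(td_update(ag, cfg, c(1, NA, 0, 0), 0, b$Phi[1, ]), "finite")
})

test_that("TD(lambda) over the identity basis equals the tabular oracle", {
  gw <- random_world(4, 3, n_wall_segments = 3, seed = 5, goal = 12)
  traj <- make_fixed_trajectory(gw, n_steps = 200, seed = 8)
  expect_gte(nrow(traj), 200)
  b <- tabular_basis(n_states(gw))
  for (lam in c(0, 0.5, 0.9)) {
    cfg <- agent_config(alpha = 0.2, gamma = 0.92, lambda = lam)
    ag <- run_td_along(traj, b, cfg)
    V_oracle <- tabular_td_oracle(traj, n_states(gw), alpha = 0.2,
                                  gamma = 0.92, lambda = lam)
    expect_equal(ag$w, V_oracle, tolerance = 1e-12)
  }
})

test_that("q-values are the neighbors' values, walls excluded", {
  gw <- grid_world(3, 3, blocked = cbind(5L, 6L), goal = 9)
  b <- tabular_basis(9)
  w <- rep(0.7, 9)
  q <- q_values(gw, b, w, 5)
  expect_false("east" %in% names(q))       # wall east of center
  expect_true(all(q == 0.7))               # equal neighbor values
  # with DP ground truth on a corridor, argmax Q points toward the goal
  corr <- grid_world(6, 1, goal = 6)
  vm <- ground_truth_dp(corr, gamma = 0.9)
  qc <- q_values(corr, tabular_basis(6), vm$values, 3)
  expect_equal(names(which.max(qc)), "east")
})

test_that("softmax policy has the closed-form choice probabilities", {
  q <- c(north = 0.2, south = 0.2 + 0.03)
  p <- softmax_probs(q, beta = 40)
  expect_equal(unname(p["south"]), 1 / (1 + exp(-40 * 0.03)))
  expect_equal(sum(p), 1)
  # beta = 0: uniform
  expect_equal(unname(softmax_probs(c(a = 1, b = 5, c = -2), 0)),
               rep(1 / 3, 3))
  # large beta concentrates on the argmax
  expect_gt(softmax_probs(q, 1e4)[["south"]], 1 - 1e-10)
  # sampling respects the probabilities deterministically given the draw
  set.seed(1)
  draws <- replicate(2000, softmax_policy(q, 40))
  expect_equal(mean(draws == "south"), p[["south"]], tolerance = 0.05)
  expect_error(softmax_policy(numeric(0), 1), "no available")
})

test_that("discount scaling follows 0.9^(d/c)", {
  expect_equal(scaled_discount(10, 10), 0.9)
  expect_equal(scaled_discount(10, 20), sqrt(0.9))
  # gamma^c = 0.9^d across worlds sharing d
  d <- 17
  for (cc in c(20, 50, 105)) {
    expect_equal(scaled_discount(d, cc)^cc, 0.9^d)
  }
  expect_error(scaled_discount(0, 5))
})

test_that("run_trial terminates, caps steps, and is seed-reproducible", {
  gw <- build_layout("open_field", 5, 5, goal = 13)
  b <- tabular_basis(25)
  cfg <- agent_config(alpha = 0.4, gamma = 0.9, lambda = 0.9, beta = 80,
                      max_steps = 40)
  set.seed(3)
  out1 <- run_trial(gw, b, agent_state(25), cfg)
  expect_lte(out1$steps, 40)
  expect_equal(length(out1$trajectory), out1$steps + 1)
  set.seed(3)
  out2 <- run_trial(gw, b, agent_state(25), cfg)
  expect_identical(out1$trajectory, out2$trajectory)
  expect_identical(out1$agent$w, out2$agent$w)
  # a goal-adjacent start can finish in one step
  adj <- gw_step(gw, 12, "east")
  expect_true(adj$terminal)
  set.seed(10)
  res <- replicate(30, run_trial(gw, b, agent_state(25), cfg, start = 12)$steps)
  expect_true(any(res == 1))
})

test_that("the compiled engine reproduces run_trial exactly", {
  gw <- make_fixture("simple_barrier_20")
  for (fam in c("tabular", "place")) {
    b <- build_basis(gw, fam)
    cfg <- agent_config(alpha = 0.3, gamma = discount_for_world(gw),
                        lambda = 0.9, beta = 80, max_steps = 500)
    set.seed(42)
    ag <- agent_state(ncol(b$Phi))
    r_steps <- integer(3)
    for (t in 1:3) {
      out <- run_trial(gw, b, ag, cfg)
      ag <- out$agent
      r_steps[t] <- out$steps
    }
    res <- td_train(gw, b, cfg, n_runs = 1, n_trials = 3, seed = 42)
    expect_identical(as.integer(res$steps[1, ]), r_steps)
    expect_equal(res$weights[1, ], ag$w, tolerance = 1e-12)
  }
})

test_that("weights stay finite and learning improves on the open field", {
  gw <- make_fixture("open_field_20")
  b <- build_basis(gw, "tabular")
  cfg <- agent_config(alpha = lookup_alpha("open_field_20", "tabular", "euclidean"),
                      gamma = discount_for_world(gw), lambda = 0.9, beta = 80)
  res <- td_train(gw, b, cfg, n_runs = 30, n_trials = 50, seed = 2)
  expect_true(all(is.finite(res$weights)))
  # mean steps over the last trial block well below the first block
  first <- mean(res$steps[, 1:5]); last <- mean(res$steps[, 46:50])
  expect_lt(last, first / 2)
})
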