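test_that("reward components reflect improvement and clamp to [0, 1]", {
  cfg <- noiseless_config()
  st <- env_reset(class_iii_record(), cfg)
  a <- null_intervention()
  s_same <- st
  r <- reward_components(st, a, s_same)
  expect_equal(unname(r[["functional"]]), 0)
  expect_equal(unname(r[["aesthetic"]]), 0)

  # full-scale harmony improvement saturates the aesthetic reward
  s_hi <- st; s_hi$soft_tissue$facial_harmony <- 10
  s_lo <- st; s_lo$soft_tissue$facial_harmony <- 0
  expect_equal(unname(reward_components(s_lo, a, s_hi)[["aesthetic"]]), 1)

  # worst-case stability
  s_bad <- st
  s_bad$treatment_status$relapse_risk <- 1
  s_bad$treatment_status$tissue_adaptation <- 0
  expect_equal(unname(reward_components(st, a, s_bad)[["stability"]]), 0)

  # components always within [0, 1] over random transitions
  env <- treatment_env(small_cohort(3), env_config())
  set.seed(21)
  traj <- rollout_episode(env, random_policy())
  for (tr in traj) {
    expect_true(all(tr$reward >= 0 & tr$reward <= 1))
  }
})

test_that("aggregate_reward is the simplex-weighted sum", {
  w <- task_weights()
  expect_equal(aggregate_reward(c(1, 1, 1, 1), w), 1)
  expect_equal(aggregate_reward(c(1, 0, 0, 0), w), 0.3)
  expect_equal(aggregate_reward(rep(0.5, 4), w), 0.5)
  expect_error(task_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
  # linearity in r and in w
  set.seed(1)
  for (i in 1:20) {
    r1 <- runif(4); r2 <- runif(4); a <- runif(1)
    expect_equal(aggregate_reward(a * r1 + (1 - a) * r2, w),
                 a * aggregate_reward(r1, w) +
                   (1 - a) * aggregate_reward(r2, w))
  }
})

test_that("TPQS reproduces hand arithmetic and the printed scale", {
  w <- task_weights()
  expect_equal(compute_tpqs(c(25, 25, 25, 25), w), 100)
  expect_equal(compute_tpqs(c(0, 0, 0, 0), w), 0)
  expect_equal(compute_tpqs(c(20, 15, 10, 5), w), 53.0)
  expect_error(compute_tpqs(c(26, 0, 0, 0), w), "\\[0, 25\\]")
})

test_that("TPQS bounds and monotonicity hold over 10,000 random inputs", {
  set.seed(7)
  w <- task_weights()
  Q <- matrix(runif(40000, 0, 25), ncol = 4)
  v <- apply(Q, 1, compute_tpqs, w = w)
  expect_true(all(v >= 0 & v <= 100))
  j <- sample.int(4, 10000L, replace = TRUE)
  bump <- runif(10000L) * (25 - Q[cbind(seq_len(10000L), j)])
  Q2 <- Q; Q2[cbind(seq_len(10000L), j)] <- Q[cbind(seq_len(10000L), j)] + bump
  v2 <- apply(Q2, 1, compute_tpqs, w = w)
  expect_true(all(v2 >= v - 1e-12))
})

test_that("permuting components together with weights leaves scores unchanged", {
  set.seed(3)
  for (i in 1:50) {
    r <- runif(4); q <- runif(4, 0, 25)
    wv <- runif(4); wv <- wv / sum(wv)
    p <- sample.int(4)
    w1 <- task_weights(wv[1], wv[2], wv[3], wv[4])
    w2 <- task_weights(wv[p][1], wv[p][2], wv[p][3], wv[p][4])
    expect_equal(aggregate_reward(r, w1), aggregate_reward(r[p], w2))
    expect_equal(compute_tpqs(q, w1), compute_tpqs(q[p], w2))
  }
})

test_that("printed comparative arithmetic is reproduced exactly", {
  expect_equal(relative_improvement(87.3, 72.8), 19.9)
  expect_equal(relative_improvement(87.3, 79.4), 9.9)
  expect_equal(relative_improvement(5, 5), 0.0)
  expect_error(relative_improvement(1, 0), "> 0")
  expect_equal(time_reduction(47.6, 12.4), 73.9)
  expect_equal(time_reduction(10, 10), 0.0)
  expect_equal(time_reduction(10, 0), 100.0)
  expect_error(time_reduction(0, 1), "> 0")
})

test_that("final-state TPQS inputs stay on the 0-25 point scales", {
  env <- treatment_env(small_cohort(3), env_config())
  set.seed(5)
  traj <- rollout_episode(env, random_policy())
  q <- tpqs_input_from_state(traj[[length(traj)]]$next_state)
  expect_length(q, 4L)
  expect_true(all(q >= 0 & q <= 25))
})
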