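test_that("state encoding is deterministic with one block per task", {
  agent <- agent_init(state_feature_dim(), seed = 1)
  st <- env_reset(class_iii_record(), noiseless_config())
  f <- state_features(st, 26.3)
  e1 <- encode_state(f, agent)
  e2 <- encode_state(f, agent)
  expect_identical(e1, e2)
  expect_length(e1$task_specific, 4L)
  expect_equal(ncol(e1$shared), 64L)
  expect_error(encode_state(numeric(3), agent), "dimension")

  # zero parameters with zero bias give the zero encoding
  agent0 <- agent
  agent0$q1 <- orthoplanr:::tree_map(function(x) x * 0, agent0$q1)
  e0 <- encode_state(f, agent0)
  expect_true(all(e0$shared == 0))
})

test_that("q_vector is the element-wise twin minimum with 4 task outputs", {
  agent <- agent_init(state_feature_dim(), seed = 2)
  st <- env_reset(class_ii_record(), noiseless_config())
  a <- random_action()
  # identical twins: min equals either critic
  agent$q2 <- agent$q1
  q <- q_vector(st, a, agent)
  expect_length(q, 4L)
  U <- matrix(c(state_features(st, 26.3), orthoplanr:::encode_action(a)),
              nrow = 1)
  expect_equal(q, as.numeric(orthoplanr:::critic_forward(agent$q1, U)$Q))

  # constant-output twins: (1,2,3,4) vs (2,1,4,3) -> (1,1,3,3)
  zero_critic <- function(agent_q, vals) {
    cz <- orthoplanr:::tree_map(function(x) x * 0, agent_q)
    for (i in 1:4) cz$heads[[i]]$o$b[1, 1] <- vals[i]
    cz
  }
  agent$q1 <- zero_critic(agent$q1, c(1, 2, 3, 4))
  agent$q2 <- zero_critic(agent$q2, c(2, 1, 4, 3))
  expect_equal(q_vector(st, a, agent), c(1, 1, 3, 3))
})

test_that("scalarize is the simplex dot product", {
  expect_equal(scalarize(c(1, 1, 1, 1), task_weights()), 1)
  expect_equal(scalarize(c(7, 0, 0, 0), task_weights(1, 0, 0, 0)), 7)
  expect_equal(scalarize(c(0.3, 0.1, 0.4, 0.2), rep(0.25, 4)), 0.25)
  expect_error(scalarize(c(1, 1), task_weights()), "length")
})

test_that("sampled actions respect the action-space bounds", {
  agent <- agent_init(state_feature_dim(), seed = 3)
  st <- env_reset(class_iii_record(), noiseless_config())
  set.seed(10)
  n_draws <- 10000L
  X <- matrix(state_features(st, 26.3), n_draws, state_feature_dim(),
              byrow = TRUE)
  sm <- orthoplanr:::policy_sample_raw(agent$policy, X, agent$space)
  expect_true(all(abs(sm$cont) <= 1))          # tanh units
  expect_true(all(sm$cat_idx >= 1L))
  expect_true(all(is.finite(sm$logp)))
  # decoded physical actions lie in the published bounds
  for (i in seq_len(200L)) {
    a <- orthoplanr:::decode_action(as.numeric(sm$cont[i, ]),
                                    as.integer(sm$cat_idx[i, ]))
    expect_true(a$jaw[1] >= -15 && a$jaw[1] <= 15)
    expect_true(a$jaw[2] >= -10 && a$jaw[2] <= 10)
    expect_true(a$jaw[3] >= -8 && a$jaw[3] <= 8)
    expect_true(a$force_magnitude >= 50 && a$force_magnitude <= 300)
    expect_true(a$interval_weeks >= 4 && a$interval_weeks <= 8)
    expect_equal(sqrt(sum(a$force_direction^2)), 1, tolerance = 1e-9)
  }
  # deterministic mode is reproducible; categorical log-probs are <= 0
  d1 <- policy_sample(st, agent, deterministic = TRUE)
  d2 <- policy_sample(st, agent, deterministic = TRUE)
  expect_identical(d1$action, d2$action)
  s1 <- policy_sample(st, agent, seed = 7)
  s2 <- policy_sample(st, agent, seed = 7)
  expect_identical(s1$action, s2$action)
})

test_that("a zero learning rate leaves parameters unchanged", {
  agent <- agent_init(4L, agent_space(0L, 3L, enumerate = TRUE),
                      spec = encoder_spec(shared_layers = 16L,
                                          task_layer = 8L), seed = 4)
  batch <- list(S = diag(4), A = rbind(c(1, 0, 0), c(0, 1, 0),
                                                    c(0, 0, 1), c(1, 0, 0)),
                R = matrix(0.5, 4, 4), S2 = diag(4)[c(2, 3, 4, 1), ],
                D = rep(0, 4))
  cfg <- train_config(steps = 1, lr = 1e-12, lr_alpha = 0,
                      fixed_alpha = 0.01, batch_size = 4, tau = 1e-12,
                      seed = 1)
  set.seed(1)
  upd <- sac_update(agent, batch, cfg)
  expect_equal(upd$agent$q1$trunk[[1]]$W, agent$q1$trunk[[1]]$W,
               tolerance = 1e-8)
  expect_equal(upd$agent$policy$trunk[[1]]$W, agent$policy$trunk[[1]]$W,
               tolerance = 1e-8)
  expect_true(all(is.finite(upd$diag)))
})

test_that("myopic critics regress onto the scalarizable immediate reward", {
  # gamma = 0 and zero temperature: the critic target is exactly r_i
  set.seed(5)
  S <- diag(4)
  batch <- list(S = S, A = rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)),
                R = matrix(runif(16), 4, 4), S2 = S[c(2, 1, 4, 3), ],
                D = rep(0, 4))
  agent <- agent_init(4L, agent_space(0L, 2L, enumerate = TRUE),
                      spec = encoder_spec(shared_layers = 32L,
                                          task_layer = 16L), seed = 6)
  cfg <- train_config(steps = 1, gamma = 0, lr = 3e-3, fixed_alpha = 0,
                      batch_size = 4, tau = 0.01, seed = 1)
  set.seed(2)
  for (i in 1:600) agent <- sac_update(agent, batch, cfg)$agent
  U <- cbind(batch$S, batch$A)
  q1 <- orthoplanr:::critic_forward(agent$q1, U)$Q
  expect_lt(max(abs(q1 - batch$R)), 0.05)
})

test_that("multitask_return satisfies its arithmetic identities", {
  mk_traj <- function(R) {
    tr <- lapply(seq_len(nrow(R)), function(t)
      list(reward = R[t, ], state = NULL, action = NULL))
    class(tr) <- "trajectory"
    tr
  }
  w <- task_weights()
  one <- mk_traj(matrix(c(1, 0, 0, 0), 1))
  expect_equal(multitask_return(list(one), w, gamma = 0.99), 0.3)

  const <- mk_traj(matrix(0.5, 10, 4))
  expect_equal(multitask_return(list(const), w, gamma = 1), 0.5 * 10)

  set.seed(8)
  R <- matrix(runif(20), 5, 4)
  tr <- mk_traj(R)
  basis <- diag(4)
  J_basis <- vapply(1:4, function(i)
    multitask_return(list(tr), basis[i, ], gamma = 0.9), numeric(1))
  expect_equal(multitask_return(list(tr), as.numeric(w), gamma = 0.9),
               sum(as.numeric(w) * J_basis))
})

test_that("training is reproducible and logs at the configured cadence", {
  mdp <- two_state_mdp()
  cfg <- train_config(steps = 600, warmup_steps = 100, batch_size = 32,
                      lr = 1e-3, fixed_alpha = 0.02, gamma = 0.5,
                      eval_every = 200, update_every = 2, seed = 31)
  r1 <- train_planner(mdp_rl_env(mdp), cfg)
  r2 <- train_planner(mdp_rl_env(mdp), cfg)
  expect_equal(nrow(r1$log), 3L)  # 600 / 200
  expect_identical(r1$log, r2$log)
  expect_identical(r1$agent$policy, r2$agent$policy)
})
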