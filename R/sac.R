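# Soft actor-critic training: replay buffer, the SAC update rule for the
# hybrid multi-task setting, and the end-to-end training loop. In the actor
# loss the categorical sub-policies are relaxed to their probability
# vectors (the critic is evaluated on soft category encodings), which gives
# exact, deterministic gradients without Gumbel sampling; purely discrete
# enumerable action spaces instead use exact expectations over all actions
# (discrete SAC).

#' Training configuration
#'
#' @param steps total environment steps
#' @param gamma discount factor
#' @param lr learning rate (Adam) for policy and critics
#' @param lr_alpha learning rate of the entropy temperature
#' @param batch_size minibatch size
#' @param replay_capacity replay-buffer capacity
#' @param warmup_steps uniform-random exploration steps before updates start
#' @param update_every environment steps per gradient update
#' @param tau soft target-update rate
#' @param target_entropy entropy target for temperature auto-tuning
#'   (default: `-n_cont + 0.35 * sum(log(cat_sizes))` in normalized action
#'   units); set `fixed_alpha` to disable auto-tuning
#' @param fixed_alpha optional fixed temperature (disables auto-tuning)
#' @param weights a [task_weights()] used for scalarization during training
#' @param eval_every record a training-log row every this many steps
#' @param seed master seed; training is bit-reproducible for serial CPU
#'   execution under a fixed seed
#' @return a `train_config` list
#' @export
train_config <- function(steps = 50000L, gamma = 0.99, lr = 3e-4,
                         lr_alpha = 3e-4, batch_size = 256L,
                         replay_capacity = 100000L, warmup_steps = 1000L,
                         update_every = 1L, tau = 0.005,
                         target_entropy = NULL, fixed_alpha = NULL,
                         weights = task_weights(), eval_every = 5000L,
                         seed = 1L) {
  # gamma = 0 is admitted as the myopic limit
  if (gamma < 0 || gamma > 1) stop_config("gamma", "must lie in [0, 1]")
  for (f in c("steps", "lr", "batch_size", "replay_capacity", "tau"))
    if (get(f) <= 0) stop_config(f, "must be positive")
  if (lr_alpha < 0) stop_config("lr_alpha", "must be >= 0")
  structure(as.list(environment()), class = "train_config")
}

# Transitions are stored as one flat row vector per environment binding:
# environments are mutated by reference, so adds are O(1) and never copy
# the buffer (row-assignment into a large env-stored matrix would
# duplicate it on every write under R's copy-on-modify rules).
replay_new <- function(capacity, nf, na_enc, n_tasks) {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv(), size = as.integer(capacity))
  e$n <- 0L; e$ptr <- 0L; e$cap <- as.integer(capacity)
  e$nf <- as.integer(nf); e$na <- as.integer(na_enc)
  e$nt <- as.integer(n_tasks)
  e
}

replay_add <- function(buf, s, a_enc, r, s2, done) {
  buf$ptr <- (buf$ptr %% buf$cap) + 1L
  assign(as.character(buf$ptr), c(s, a_enc, r, s2, as.numeric(done)),
         envir = buf$store)
  buf$n <- min(buf$n + 1L, buf$cap)
  invisible(buf)
}

replay_sample <- function(buf, m) {
  idx <- sample.int(buf$n, m, replace = buf$n < m)
  rows <- mget(as.character(idx), envir = buf$store)
  M <- matrix(unlist(rows, use.names = FALSE), nrow = m, byrow = TRUE)
  nf <- buf$nf; na <- buf$na; nt <- buf$nt
  list(S = M[, seq_len(nf), drop = FALSE],
       A = M[, nf + seq_len(na), drop = FALSE],
       R = M[, nf + na + seq_len(nt), drop = FALSE],
       S2 = M[, nf + na + nt + seq_len(nf), drop = FALSE],
       D = M[, nf + na + nt + nf + 1L])
}

default_target_entropy <- function(space) {
  -space$n_cont + if (space$n_cat > 0L) 0.35 * sum(log(space$cat_sizes)) else 0
}

# all joint categorical actions as one-hot rows (enumerable spaces only)
enumerate_actions <- function(space) {
  grids <- lapply(space$cat_sizes, seq_len)
  combos <- as.matrix(expand.grid(grids))
  onehots <- cat_onehot(combos, space)
  list(idx = combos, enc = onehots, K = nrow(combos))
}

#' One SAC gradient update
#'
#' Critic targets bootstrap the scalarizable per-task values:
#' `y_i = r_i + gamma * (1 - done) * (minQ'_i(s', a') - alpha * log pi(a'|s'))`
#' with `a'` sampled from the current policy (exact expectation over actions
#' for enumerable discrete spaces). The actor minimizes
#' `alpha * log pi(a|s) - sum_i w_i minQ_i(s, a)` with reparameterized
#' continuous actions and soft categorical relaxation; the temperature is
#' adjusted toward the entropy target; target critics are soft-updated.
#'
#' @param agent an [agent_init()] result
#' @param batch list with matrices `S`, `A` (encoded actions), `R`
#'   (per-task rewards), `S2`, and numeric `D` (done flags)
#' @param config a [train_config()]
#' @return list `agent` (updated), `diag` (named losses; all finite or an
#'   error is raised)
#' @export
sac_update <- function(agent, batch, config) {
  space <- agent$space
  n <- nrow(batch$S)
  if (n < 1L) stop("batch must be non-empty", call. = FALSE)
  w <- as.numeric(config$weights)
  nt <- agent$spec$n_tasks
  if (length(w) != nt) stop("weights length must match task count", call. = FALSE)
  alpha <- if (!is.null(config$fixed_alpha)) config$fixed_alpha
           else exp(agent$log_alpha)
  gamma <- config$gamma

  # ---- critic targets ----------------------------------------------------
  if (space$enumerate && space$n_cont == 0L) {
    enum <- enumerate_actions(space)
    pf2 <- policy_forward(agent$policy, batch$S2, space)
    P2 <- do.call(cbind, lapply(seq_len(enum$K), function(k) {
      pk <- rep(1, n)
      for (g in seq_len(space$n_cat)) pk <- pk * pf2$probs[[g]][, enum$idx[k, g]]
      pk
    }))
    V2 <- matrix(0, n, nt)
    for (k in seq_len(enum$K)) {
      U2k <- cbind(batch$S2, matrix(enum$enc[k, ], n, space$enc_dim,
                                    byrow = TRUE))
      qk <- pmin(critic_forward(agent$q1_targ, U2k)$Q,
                 critic_forward(agent$q2_targ, U2k)$Q)
      V2 <- V2 + P2[, k] * (qk - alpha * log(P2[, k] + 1e-12))
    }
    y <- batch$R + gamma * (1 - batch$D) * V2
    logp_now <- NULL
  } else {
    sm2 <- policy_sample_raw(agent$policy, batch$S2, space)
    a2_enc <- cbind(
      if (space$n_cont > 0L) sm2$cont,
      if (space$n_cat > 0L) cat_onehot(sm2$cat_idx, space))
    U2 <- cbind(batch$S2, a2_enc)
    qt <- pmin(critic_forward(agent$q1_targ, U2)$Q,
               critic_forward(agent$q2_targ, U2)$Q)
    y <- batch$R + gamma * (1 - batch$D) * (qt - alpha * sm2$logp)
  }

  # ---- critic update -----------------------------------------------------
  U <- cbind(batch$S, batch$A)
  c1 <- critic_forward(agent$q1, U)
  c2 <- critic_forward(agent$q2, U)
  e1 <- c1$Q - y; e2 <- c2$Q - y
  q_loss <- mean(e1^2) + mean(e2^2)
  g1 <- critic_backward(agent$q1, c1, 2 * e1 / (n * nt))$grads
  g2 <- critic_backward(agent$q2, c2, 2 * e2 / (n * nt))$grads
  st1 <- adam_step(agent$q1, g1, agent$opt$q1, config$lr)
  st2 <- adam_step(agent$q2, g2, agent$opt$q2, config$lr)
  agent$q1 <- st1$params; agent$opt$q1 <- st1$opt
  agent$q2 <- st2$params; agent$opt$q2 <- st2$opt

  # ---- actor update ------------------------------------------------------
  if (space$enumerate && space$n_cont == 0L) {
    enum <- enumerate_actions(space)
    pf <- policy_forward(agent$policy, batch$S, space)
    QS <- matrix(0, n, enum$K)        # scalarized minQ for each action
    for (k in seq_len(enum$K)) {
      Uk <- cbind(batch$S, matrix(enum$enc[k, ], n, space$enc_dim,
                                  byrow = TRUE))
      qk <- pmin(critic_forward(agent$q1, Uk)$Q,
                 critic_forward(agent$q2, Uk)$Q)
      QS[, k] <- qk %*% w
    }
    # single categorical group in the enumerable branch
    P <- pf$probs[[1L]]
    pi_loss <- mean(rowSums(P * (alpha * log(P + 1e-12) - QS)))
    dLdp <- (alpha * (log(P + 1e-12) + 1) - QS) / n
    dlog <- P * (dLdp - rowSums(P * dLdp))
    bl <- dense_bwd(pf$H, agent$policy$logits, dlog)
    dH <- bl$dX
    tb <- trunk_backward(agent$policy$trunk, pf$trunk_acts, dH)
    pgrads <- list(trunk = tb$grads, logits = bl$grad)
    logp_mean <- mean(rowSums(P * log(P + 1e-12)))
  } else {
    sm <- policy_sample_raw(agent$policy, batch$S, space)
    pf <- sm$pf
    probs_flat <- if (space$n_cat > 0L) do.call(cbind, pf$probs)
    U_pi <- cbind(batch$S,
                  if (space$n_cont > 0L) sm$cont,
                  probs_flat)
    cf1 <- critic_forward(agent$q1, U_pi)
    cf2 <- critic_forward(agent$q2, U_pi)
    qmin <- pmin(cf1$Q, cf2$Q)
    use1 <- cf1$Q <= cf2$Q
    # negative-entropy of the categorical part is an exact expectation
    cat_neg_ent <- if (space$n_cat > 0L)
      rowSums(probs_flat * log(probs_flat + 1e-12)) else 0
    logp_cont <- if (space$n_cont > 0L) sm$logp else 0
    pi_loss <- mean(alpha * (logp_cont + cat_neg_ent) - qmin %*% w)

    dQ <- -matrix(w, n, nt, byrow = TRUE) / n
    b1 <- critic_backward(agent$q1, cf1, dQ * use1, need_dU = TRUE)
    b2 <- critic_backward(agent$q2, cf2, dQ * (!use1), need_dU = TRUE)
    dU <- b1$dU + b2$dU
    nf <- agent$state_dim
    dH <- matrix(0, n, ncol(pf$H))
    pgrads <- list(trunk = NULL)
    if (space$n_cont > 0L) {
      da <- dU[, nf + seq_len(space$n_cont), drop = FALSE]
      a <- sm$cont; z <- sm$z
      glp <- 2 * a * (1 - a^2) / (1 - a^2 + 1e-6)        # d logp / d z
      dz <- (alpha / n) * glp + da * (1 - a^2)
      dmu <- dz
      dls <- dz * (z - pf$mu) - (alpha / n)
      dls <- dls * pf$ls_mask
      bmu <- dense_bwd(pf$H, agent$policy$mu, dmu)
      bls <- dense_bwd(pf$H, agent$policy$ls, dls)
      dH <- dH + bmu$dX + bls$dX
      pgrads$mu <- bmu$grad; pgrads$ls <- bls$grad
    }
    if (space$n_cat > 0L) {
      dP_critic <- dU[, nf + space$n_cont + seq_len(sum(space$cat_sizes)),
                      drop = FALSE]
      dlog_all <- matrix(0, n, sum(space$cat_sizes))
      sp <- pf$logit_split
      for (g in seq_len(space$n_cat)) {
        cols <- sp$starts[g]:sp$ends[g]
        P <- pf$probs[[g]]
        dLdp <- dP_critic[, cols, drop = FALSE] +
          (alpha / n) * (log(P + 1e-12) + 1)
        dlog_all[, cols] <- P * (dLdp - rowSums(P * dLdp))
      }
      blg <- dense_bwd(pf$H, agent$policy$logits, dlog_all)
      dH <- dH + blg$dX
      pgrads$logits <- blg$grad
    }
    tb <- trunk_backward(agent$policy$trunk, pf$trunk_acts, dH)
    pgrads$trunk <- tb$grads
    logp_mean <- mean(logp_cont + cat_neg_ent)
  }
  stp <- adam_step(agent$policy, pgrads[names(agent$policy)],
                   agent$opt$policy, config$lr)
  agent$policy <- stp$params; agent$opt$policy <- stp$opt

  # ---- temperature -------------------------------------------------------
  if (is.null(config$fixed_alpha)) {
    h_targ <- config$target_entropy %||% default_target_entropy(space)
    agent$log_alpha <- agent$log_alpha +
      config$lr_alpha * (logp_mean + h_targ)
    agent$log_alpha <- clamp(agent$log_alpha, -10, 2)
  }

  # ---- target networks ---------------------------------------------------
  agent$q1_targ <- soft_update(agent$q1_targ, agent$q1, config$tau)
  agent$q2_targ <- soft_update(agent$q2_targ, agent$q2, config$tau)

  diag <- c(q_loss = q_loss, pi_loss = pi_loss, alpha = alpha,
            logp = logp_mean)
  if (any(!is.finite(diag)))
    stop("training diverged (non-finite loss): ",
         paste(sprintf("%s=%.3g", names(diag), diag), collapse = ", "),
         call. = FALSE)
  list(agent = agent, diag = diag)
}

#' Adapter exposing a treatment environment to the planner
#'
#' @param env a [treatment_env()]
#' @return an `rl_env` list with `reset`, `step_enc` (takes tanh-unit
#'   continuous vector and categorical indices), `space`, `feature_dim`,
#'   `n_tasks`
#' @export
treatment_rl_env <- function(env) {
  h <- env$config$horizon_months
  list(
    reset = function(i = NULL) state_features(env$reset(i), h),
    step_enc = function(cont, cat_idx) {
      a <- decode_action(cont, cat_idx)
      out <- env$step(a)
      list(features = state_features(out$next_state, h),
           reward = as.numeric(out$reward), done = out$done)
    },
    random_enc = function() {
      list(cont = stats::runif(CONT_DIM, -1, 1),
           cat_idx = vapply(unname(CAT_SIZES),
                            function(k) sample.int(k, 1L), integer(1)))
    },
    space = treatment_agent_space(),
    feature_dim = state_feature_dim(), n_tasks = 4L
  )
}

#' Train a multi-task SAC planner
#'
#' Seeded end-to-end: uniform exploration for the warmup period, then
#' interleaved environment steps and SAC updates from a replay buffer. The
#' training log records interval statistics of the scalarized and per-task
#' returns of completed training episodes.
#'
#' @param rl_env an environment adapter (e.g. [treatment_rl_env()] or
#'   [mdp_rl_env()])
#' @param config a [train_config()]
#' @param agent optionally, a pre-initialized agent to continue training
#' @return list with `agent` and `log` (data frame: step, mean scalarized
#'   return, per-task returns, losses)
#' @export
train_planner <- function(rl_env, config = train_config(), agent = NULL) {
  set.seed(config$seed)
  space <- rl_env$space
  if (is.null(agent))
    agent <- agent_init(rl_env$feature_dim, space,
                        spec = encoder_spec(n_tasks = rl_env$n_tasks),
                        seed = derive_seed(config$seed, 97L))
  buf <- replay_new(min(config$replay_capacity, config$steps),
                    rl_env$feature_dim, space$enc_dim, rl_env$n_tasks)
  w <- as.numeric(config$weights)

  s <- rl_env$reset()
  ep_r <- matrix(0, 0, rl_env$n_tasks)
  ep_acc <- numeric(rl_env$n_tasks); ep_t <- 0L; ep_disc <- 1
  log_rows <- list()
  last_diag <- c(q_loss = NA_real_, pi_loss = NA_real_, alpha = NA_real_,
                 logp = NA_real_)

  for (step in seq_len(config$steps)) {
    if (step <= config$warmup_steps) {
      re <- rl_env$random_enc()
      cont <- re$cont; cat_idx <- re$cat_idx
    } else {
      sm <- policy_sample_raw(agent$policy, matrix(s, nrow = 1), space)
      cont <- if (space$n_cont > 0L) as.numeric(sm$cont) else numeric()
      cat_idx <- if (space$n_cat > 0L) as.integer(sm$cat_idx) else integer()
    }
    out <- rl_env$step_enc(cont, cat_idx)
    a_enc <- c(cont, if (space$n_cat > 0L)
      as.numeric(cat_onehot(matrix(cat_idx, 1), space)))
    # truncated (time-limited) episodes keep bootstrapping in the targets
    store_done <- out$done && !isTRUE(out$trunc)
    replay_add(buf, s, a_enc, out$reward, out$features, store_done)
    ep_acc <- ep_acc + ep_disc * out$reward
    ep_disc <- ep_disc * config$gamma
    ep_t <- ep_t + 1L
    if (out$done) {
      ep_r <- rbind(ep_r, ep_acc)
      ep_acc <- numeric(rl_env$n_tasks); ep_disc <- 1; ep_t <- 0L
      s <- rl_env$reset()
    } else s <- out$features

    if (step > config$warmup_steps && step %% config$update_every == 0L &&
        buf$n >= config$batch_size) {
      upd <- sac_update(agent, replay_sample(buf, config$batch_size), config)
      agent <- upd$agent
      last_diag <- upd$diag
    }

    if (step %% config$eval_every == 0L) {
      recent <- if (nrow(ep_r) > 0L)
        ep_r[max(1L, nrow(ep_r) - 19L):nrow(ep_r), , drop = FALSE]
      else matrix(NA_real_, 1, rl_env$n_tasks)
      row <- data.frame(step = step,
                        return_scalar = mean(recent %*% w),
                        t(colMeans(recent)),
                        q_loss = last_diag[["q_loss"]],
                        pi_loss = last_diag[["pi_loss"]],
                        alpha = last_diag[["alpha"]])
      names(row)[3:(2 + rl_env$n_tasks)] <-
        paste0("return_task", seq_len(rl_env$n_tasks))
      log_rows[[length(log_rows) + 1L]] <- row
    }
  }
  list(agent = agent, log = do.call(rbind, log_rows))
}

#' Empirical multi-task return of a trajectory set
#'
#' Mean over trajectories of the discounted weighted reward sum
#' `sum_t gamma^t sum_i w_i r_{i,t}`; exactly equals the weighted sum of
#' per-task returns.
#'
#' @param trajectories list of trajectories (each a list of steps carrying
#'   `reward` vectors), e.g. from [rollout_episode()]
#' @param w a [task_weights()]
#' @param gamma discount factor
#' @return scalar estimate of the scalarized objective
#' @export
multitask_return <- function(trajectories, w = task_weights(), gamma = 0.99) {
  if (length(trajectories) == 0L) stop("need at least one trajectory",
                                       call. = FALSE)
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  w <- as.numeric(w)
  mean(vapply(trajectories, function(tr) {
    disc <- gamma^(seq_along(tr) - 1)
    sum(disc * vapply(tr, function(x) sum(w * as.numeric(x$reward)),
                      numeric(1)))
  }, numeric(1)))
}

#' Per-task discounted returns of one trajectory
#' @param traj a trajectory
#' @param gamma discount factor
#' @return numeric vector of per-task returns
#' @export
task_returns <- function(traj, gamma = 0.99) {
  disc <- gamma^(seq_along(traj) - 1)
  R <- t(vapply(traj, function(x) as.numeric(x$reward),
                numeric(length(traj[[1]]$reward))))
  as.numeric(disc %*% R)
}

#' Evaluate a policy on a treatment environment
#'
#' Runs `n_episodes` seeded episodes (cycling the cohort) and collects the
#' scalarized return, per-task returns and final-state TPQS for each.
#'
#' @param env a [treatment_env()]
#' @param policy function `state -> treatment_action`
#' @param n_episodes number of evaluation episodes
#' @param seed evaluation seed (controls environment noise)
#' @param w a [task_weights()]
#' @param gamma discount factor
#' @return data frame with one row per episode: `return_scalar`,
#'   `return_functional` ... `return_stability`, `tpqs`, `months`
#' @export
evaluate_policy <- function(env, policy, n_episodes = 20L, seed = 1L,
                            w = task_weights(), gamma = 0.99) {
  set.seed(seed)
  env$cursor <- 0L
  rows <- lapply(seq_len(n_episodes), function(i) {
    traj <- rollout_episode(env, policy)
    tr <- task_returns(traj, gamma)
    fin <- traj[[length(traj)]]$next_state
    data.frame(episode = i, return_scalar = sum(as.numeric(w) * tr),
               return_functional = tr[1], return_aesthetic = tr[2],
               return_efficiency = tr[3], return_stability = tr[4],
               tpqs = compute_tpqs(tpqs_input_from_state(
                 fin, env$config$horizon_months), w),
               months = fin$treatment_status$elapsed_months)
  })
  do.call(rbind, rows)
}
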