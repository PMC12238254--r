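# Small enumerable MDPs: the cross-check bed for the planner. Value
# iteration is the independent oracle the learned critics are compared
# against.

#' Define a finite MDP
#'
#' @param P transition array `[n_states, n_actions, n_states]`; each
#'   `P[s, a, ]` a probability vector
#' @param R reward array `[n_states, n_actions, n_tasks]`
#' @param gamma discount factor
#' @return a `finite_mdp` list
#' @export
finite_mdp <- function(P, R, gamma = 0.9) {
  stopifnot(length(dim(P)) == 3L, dim(P)[1] == dim(P)[3],
            length(dim(R)) == 3L, dim(R)[1] == dim(P)[1],
            dim(R)[2] == dim(P)[2])
  if (max(abs(apply(P, c(1, 2), sum) - 1)) > 1e-9)
    stop("transition rows must sum to 1", call. = FALSE)
  structure(list(P = P, R = R, gamma = gamma,
                 n_states = dim(P)[1], n_actions = dim(P)[2],
                 n_tasks = dim(R)[3]), class = "finite_mdp")
}

#' Value iteration on the scalarized reward
#'
#' @param mdp a [finite_mdp()]
#' @param w simplex weights over the task rewards
#' @param tol convergence tolerance on the value function
#' @param max_iter iteration cap
#' @return list with `Q` (`n_states x n_actions`), `V`, `policy` (greedy)
#' @export
value_iteration <- function(mdp, w = rep(1 / dim(mdp$R)[3], dim(mdp$R)[3]),
                            tol = 1e-10, max_iter = 10000L) {
  S <- mdp$n_states; K <- mdp$n_actions
  Rs <- matrix(0, S, K)
  for (i in seq_len(mdp$n_tasks)) Rs <- Rs + w[i] * mdp$R[, , i]
  V <- numeric(S)
  for (it in seq_len(max_iter)) {
    Q <- Rs
    for (k in seq_len(K)) Q[, k] <- Rs[, k] + mdp$gamma * (mdp$P[, k, ] %*% V)
    Vn <- apply(Q, 1, max)
    if (max(abs(Vn - V)) < tol) { V <- Vn; break }
    V <- Vn
  }
  Q <- Rs
  for (k in seq_len(K)) Q[, k] <- Rs[, k] + mdp$gamma * (mdp$P[, k, ] %*% V)
  list(Q = Q, V = apply(Q, 1, max), policy = max.col(Q))
}

#' Exact value of a (possibly stochastic) policy on a finite MDP
#'
#' Solves the linear policy-evaluation system for the scalarized reward.
#'
#' @param mdp a [finite_mdp()]
#' @param pi_mat `n_states x n_actions` action-probability matrix
#' @param w simplex task weights
#' @return numeric state-value vector
#' @export
policy_value <- function(mdp, pi_mat, w = rep(1 / mdp$n_tasks, mdp$n_tasks)) {
  S <- mdp$n_states; K <- mdp$n_actions
  Rs <- matrix(0, S, K)
  for (i in seq_len(mdp$n_tasks)) Rs <- Rs + w[i] * mdp$R[, , i]
  Ppi <- matrix(0, S, S); rpi <- numeric(S)
  for (s in seq_len(S)) {
    for (k in seq_len(K)) {
      Ppi[s, ] <- Ppi[s, ] + pi_mat[s, k] * mdp$P[s, k, ]
      rpi[s] <- rpi[s] + pi_mat[s, k] * Rs[s, k]
    }
  }
  as.numeric(solve(diag(S) - mdp$gamma * Ppi, rpi))
}

#' Expose a finite MDP to the planner
#'
#' States are one-hot encoded; the single categorical action group is
#' enumerable, so training uses exact discrete-SAC expectations. Episodes
#' are truncated (not terminated) after `episode_len` steps so the learned
#' values estimate the infinite-horizon discounted objective that value
#' iteration computes.
#'
#' @param mdp a [finite_mdp()]
#' @param episode_len steps per episode before truncation
#' @return an `rl_env` adapter for [train_planner()]
#' @export
mdp_rl_env <- function(mdp, episode_len = 25L) {
  st <- new.env(parent = emptyenv())
  st$s <- 1L; st$t <- 0L
  onehot <- function(s) { v <- numeric(mdp$n_states); v[s] <- 1; v }
  list(
    reset = function(i = NULL) {
      st$s <- sample.int(mdp$n_states, 1L); st$t <- 0L
      onehot(st$s)
    },
    step_enc = function(cont, cat_idx) {
      k <- cat_idx[1]
      s2 <- sample.int(mdp$n_states, 1L, prob = mdp$P[st$s, k, ])
      r <- mdp$R[st$s, k, ]
      st$s <- s2; st$t <- st$t + 1L
      list(features = onehot(s2), reward = r,
           done = st$t >= episode_len, trunc = TRUE)
    },
    random_enc = function() list(cont = numeric(),
                                 cat_idx = sample.int(mdp$n_actions, 1L)),
    space = agent_space(0L, mdp$n_actions, enumerate = TRUE),
    feature_dim = mdp$n_states, n_tasks = mdp$n_tasks
  )
}

#' Greedy/soft policy matrix of a trained agent on a finite MDP
#'
#' @param agent trained agent (from [train_planner()] on [mdp_rl_env()])
#' @param mdp the [finite_mdp()]
#' @param deterministic return the greedy (one-hot) policy
#' @return `n_states x n_actions` probability matrix
#' @export
agent_mdp_policy <- function(agent, mdp, deterministic = TRUE) {
  X <- diag(mdp$n_states)
  pf <- policy_forward(agent$policy, X, agent$space)
  P <- pf$probs[[1L]]
  if (deterministic) {
    M <- matrix(0, mdp$n_states, mdp$n_actions)
    M[cbind(seq_len(mdp$n_states), max.col(P, ties.method = "first"))] <- 1
    M
  } else P
}

#' Learned scalarized Q-values on a finite MDP
#'
#' Clipped double-Q (element-wise twin minimum) per task, scalarized with
#' `w`, for every state-action pair.
#'
#' @param agent trained agent
#' @param mdp the [finite_mdp()]
#' @param w simplex task weights
#' @return `n_states x n_actions` matrix
#' @export
agent_mdp_q <- function(agent, mdp, w = rep(1 / mdp$n_tasks, mdp$n_tasks)) {
  X <- diag(mdp$n_states)
  enum <- enumerate_actions(agent$space)
  QS <- matrix(0, mdp$n_states, mdp$n_actions)
  for (k in seq_len(enum$K)) {
    U <- cbind(X, matrix(enum$enc[k, ], mdp$n_states, agent$space$enc_dim,
                         byrow = TRUE))
    q <- pmin(critic_forward(agent$q1, U)$Q, critic_forward(agent$q2, U)$Q)
    QS[, k] <- q %*% w
  }
  QS
}
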