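# Multi-task soft actor-critic agent: a squashed-Gaussian + categorical
# hybrid policy, twin vector critics with a shared encoder trunk and
# task-specific heads (one head per reward component), target critics and
# an auto-tuned entropy temperature.

LOG_STD_MIN <- -5
LOG_STD_MAX <- 2

#' Encoder architecture specification
#'
#' The critics factor the state-action representation into a shared trunk
#' and task-specific heads, one per reward component, mirroring the
#' shared/task-specific feature-extractor decomposition
#' `phi(s) = [h_shared(s), h_task_specific(s)]`.
#'
#' @param shared_layers sizes of the shared trunk layers (at least one)
#' @param task_layer size of each task-specific head layer
#' @param n_tasks number of reward components (heads)
#' @param activation activation name (`"relu"` is the implemented choice)
#' @return an `encoder_spec` list
#' @export
encoder_spec <- function(shared_layers = 64L, task_layer = 32L,
                         n_tasks = 4L, activation = "relu") {
  if (length(shared_layers) < 1L) stop("need at least one shared layer",
                                       call. = FALSE)
  if (n_tasks < 1L) stop("need one task head per reward component",
                         call. = FALSE)
  structure(list(shared_layers = as.integer(shared_layers),
                 task_layer = as.integer(task_layer),
                 n_tasks = as.integer(n_tasks), activation = activation),
            class = "encoder_spec")
}

#' Agent action-space descriptor
#'
#' @param n_cont number of continuous action dimensions (policy emits them
#'   in tanh units, mapped onto their physical bounds by the environment
#'   adapter)
#' @param cat_sizes integer vector of categorical vocabulary sizes (may be
#'   empty)
#' @param enumerate evaluate expectations over all joint categorical actions
#'   exactly (only sensible for small purely discrete spaces)
#' @return an `agent_space` list
#' @export
agent_space <- function(n_cont, cat_sizes = integer(), enumerate = FALSE) {
  structure(list(n_cont = as.integer(n_cont),
                 cat_sizes = as.integer(cat_sizes),
                 n_cat = length(cat_sizes),
                 enc_dim = as.integer(n_cont + sum(cat_sizes)),
                 enumerate = isTRUE(enumerate)),
            class = "agent_space")
}

treatment_agent_space <- function() agent_space(CONT_DIM, unname(CAT_SIZES))

policy_init <- function(nf, space, hidden = c(64L, 64L)) {
  p <- list(trunk = trunk_init(nf, hidden))
  last <- hidden[length(hidden)]
  if (space$n_cont > 0L) {
    p$mu <- dense_init(last, space$n_cont)
    p$ls <- dense_init(last, space$n_cont)
  }
  if (space$n_cat > 0L) p$logits <- dense_init(last, sum(space$cat_sizes))
  p
}

critic_init <- function(nf, space, spec) {
  list(trunk = trunk_init(nf + space$enc_dim, spec$shared_layers),
       heads = lapply(seq_len(spec$n_tasks), function(i) {
         last <- spec$shared_layers[length(spec$shared_layers)]
         list(h = dense_init(last, spec$task_layer),
              o = dense_init(spec$task_layer, 1L))
       }))
}

critic_forward <- function(params, U) {
  tf <- trunk_forward(U, params$trunk)
  H <- tf$out
  nt <- length(params$heads)
  Q <- matrix(0, nrow(U), nt)
  hcache <- vector("list", nt)
  for (i in seq_len(nt)) {
    hi <- relu(dense_fwd(H, params$heads[[i]]$h))
    Q[, i] <- dense_fwd(hi, params$heads[[i]]$o)
    hcache[[i]] <- hi
  }
  list(Q = Q, trunk_acts = tf$acts, H = H, hcache = hcache)
}

# dQ: n x n_tasks gradient at the critic outputs
critic_backward <- function(params, cache, dQ, need_dU = FALSE) {
  nt <- length(params$heads)
  H <- cache$H
  dH <- matrix(0, nrow(H), ncol(H))
  hgrads <- vector("list", nt)
  for (i in seq_len(nt)) {
    do <- dQ[, i, drop = FALSE]
    hi <- cache$hcache[[i]]
    bo <- dense_bwd(hi, params$heads[[i]]$o, do)
    dhi <- bo$dX * (hi > 0)
    bh <- dense_bwd(H, params$heads[[i]]$h, dhi)
    dH <- dH + bh$dX
    hgrads[[i]] <- list(h = bh$grad, o = bo$grad)
  }
  tb <- trunk_backward(params$trunk, cache$trunk_acts, dH)
  out <- list(grads = list(trunk = tb$grads, heads = hgrads))
  if (need_dU) out$dU <- tb$dX
  out
}

#' Initialize a multi-task SAC agent
#'
#' @param state_dim dimension of the state feature vector
#' @param space an [agent_space()]
#' @param spec an [encoder_spec()]
#' @param hidden_policy policy trunk layer sizes
#' @param init_alpha initial entropy temperature
#' @param seed integer seed for weight initialization
#' @return an `agent_params` list: policy, twin critics `q1`/`q2`, target
#'   critics, `log_alpha`, optimizer states
#' @export
agent_init <- function(state_dim, space = treatment_agent_space(),
                       spec = encoder_spec(), hidden_policy = c(64L, 64L),
                       init_alpha = 0.2, seed = 1L) {
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  policy <- policy_init(state_dim, space, hidden_policy)
  q1 <- critic_init(state_dim, space, spec)
  q2 <- critic_init(state_dim, space, spec)
  structure(list(
    space = space, spec = spec, state_dim = as.integer(state_dim),
    policy = policy, q1 = q1, q2 = q2, q1_targ = q1, q2_targ = q2,
    log_alpha = log(init_alpha),
    opt = list(policy = adam_new(policy), q1 = adam_new(q1),
               q2 = adam_new(q2))
  ), class = "agent_params")
}

#' Shared and task-specific encodings of a state
#'
#' Runs the critic's shared trunk on the state features (zero action
#' encoding) and returns the shared representation together with the
#' per-task head activations — the `[h_shared, h_task_specific]`
#' decomposition.
#'
#' @param features a `patient_state`, numeric state feature vector, or
#'   matrix of feature rows
#' @param agent an [agent_init()] result
#' @return list with `shared` and `task_specific` (one block per task)
#' @export
encode_state <- function(features, agent) {
  if (inherits(features, "patient_state"))
    features <- state_features(features)
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != agent$state_dim)
    stop(sprintf("feature dimension %d does not match agent state_dim %d",
                 ncol(X), agent$state_dim), call. = FALSE)
  U <- cbind(X, matrix(0, nrow(X), agent$space$enc_dim))
  cf <- critic_forward(agent$q1, U)
  list(shared = cf$H, task_specific = cf$hcache)
}

policy_forward <- function(params, X, space) {
  tf <- trunk_forward(X, params$trunk)
  out <- list(trunk_acts = tf$acts, H = tf$out)
  if (space$n_cont > 0L) {
    out$mu <- dense_fwd(tf$out, params$mu)
    ls_raw <- dense_fwd(tf$out, params$ls)
    out$ls <- clamp(ls_raw, LOG_STD_MIN, LOG_STD_MAX)
    out$ls_mask <- (ls_raw > LOG_STD_MIN) & (ls_raw < LOG_STD_MAX)
  }
  if (space$n_cat > 0L) {
    lg <- dense_fwd(tf$out, params$logits)
    ends <- cumsum(space$cat_sizes)
    starts <- c(1L, ends[-length(ends)] + 1L)
    out$probs <- lapply(seq_along(space$cat_sizes), function(g)
      softmax(lg[, starts[g]:ends[g], drop = FALSE]))
    out$logit_split <- list(starts = starts, ends = ends)
  }
  out
}

# Sample (or take the mode of) the policy at feature rows X.
# Log-probabilities are in normalized (tanh-unit) action coordinates.
policy_sample_raw <- function(params, X, space, deterministic = FALSE) {
  pf <- policy_forward(params, X, space)
  n <- nrow(X)
  out <- list(pf = pf, logp = numeric(n))
  if (space$n_cont > 0L) {
    sd <- exp(pf$ls)
    eps <- if (deterministic) matrix(0, n, space$n_cont)
           else matrix(stats::rnorm(n * space$n_cont), n, space$n_cont)
    z <- pf$mu + sd * eps
    a <- tanh(z)
    lp <- -0.5 * eps^2 - pf$ls - 0.5 * log(2 * pi) - log(1 - a^2 + 1e-6)
    out$cont <- a; out$z <- z; out$eps <- eps
    out$logp <- out$logp + rowSums(lp)
  }
  if (space$n_cat > 0L) {
    idx <- matrix(0L, n, space$n_cat)
    for (g in seq_len(space$n_cat)) {
      P <- pf$probs[[g]]
      if (deterministic) idx[, g] <- max.col(P, ties.method = "first")
      else {
        u <- stats::runif(n)
        k <- rep(1L, n)
        cs <- P[, 1L]
        for (cc in seq_len(ncol(P) - 1L)) {
          k <- k + (u > cs)
          if (cc < ncol(P) - 1L) cs <- cs + P[, cc + 1L]
        }
        idx[, g] <- k
      }
      out$logp <- out$logp + log(P[cbind(seq_len(n), idx[, g])] + 1e-12)
    }
    out$cat_idx <- idx
  }
  out
}

# one-hot encode sampled categorical indices
cat_onehot <- function(idx, space) {
  n <- nrow(idx)
  do.call(cbind, lapply(seq_len(space$n_cat), function(g) {
    M <- matrix(0, n, space$cat_sizes[g])
    M[cbind(seq_len(n), idx[, g])] <- 1
    M
  }))
}

#' Sample a treatment action from the policy
#'
#' Continuous sub-actions come from a squashed-Gaussian head mapped into
#' the physical bounds; categorical sub-actions from categorical heads. The
#' returned log-probability is the sum of the parts (continuous part in
#' normalized tanh units). `deterministic = TRUE` returns the mode.
#'
#' @param state a `patient_state`
#' @param agent an [agent_init()] result (with `treatment_agent_space()`)
#' @param seed optional seed for this single draw
#' @param deterministic return the distribution mode instead of a sample
#' @param horizon_months feature normalizer, matches the environment config
#' @return list with `action` (a `treatment_action`) and `logp`
#' @export
policy_sample <- function(state, agent, seed = NULL, deterministic = FALSE,
                          horizon_months = 26.3) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  X <- matrix(state_features(state, horizon_months), nrow = 1)
  sm <- policy_sample_raw(agent$policy, X, agent$space, deterministic)
  act <- decode_action(as.numeric(sm$cont), as.integer(sm$cat_idx))
  list(action = act, logp = sm$logp)
}

#' Task-value vector of a state-action pair
#'
#' Element-wise minimum of the twin critics' per-task outputs (clipped
#' double-Q), one value per reward component.
#'
#' @param state a `patient_state` (or numeric feature vector)
#' @param action a `treatment_action` (or numeric encoded action)
#' @param agent an [agent_init()] result
#' @param horizon_months feature normalizer
#' @return numeric vector of length `n_tasks`
#' @export
q_vector <- function(state, action, agent, horizon_months = 26.3) {
  x <- if (inherits(state, "patient_state"))
    state_features(state, horizon_months) else as.numeric(state)
  ae <- if (inherits(action, "treatment_action"))
    encode_action(action) else as.numeric(action)
  U <- matrix(c(x, ae), nrow = 1)
  q1 <- critic_forward(agent$q1, U)$Q
  q2 <- critic_forward(agent$q2, U)$Q
  as.numeric(pmin(q1, q2))
}

#' Scalarize a task-value vector
#'
#' @param q numeric vector of per-task values
#' @param w a [task_weights()] (or any simplex weights of matching length)
#' @return the dot product `sum(w * q)`
#' @export
scalarize <- function(q, w = task_weights()) {
  w <- as.numeric(w)
  if (abs(sum(w) - 1) > 1e-9) stop("weights must lie on the simplex",
                                   call. = FALSE)
  if (length(q) != length(w)) stop("length mismatch between q and w",
                                   call. = FALSE)
  sum(w * as.numeric(q))
}

#' Deterministic planner policy over patient states
#'
#' @param agent a trained agent
#' @param deterministic use the policy mode (default) or sample
#' @param horizon_months feature normalizer
#' @return a function `patient_state -> treatment_action`
#' @export
planner_policy <- function(agent, deterministic = TRUE, horizon_months = 26.3) {
  function(state)
    policy_sample(state, agent, deterministic = deterministic,
                  horizon_months = horizon_months)$action
}

#' Uniform random baseline policy
#'
#' @return a function `patient_state -> treatment_action` drawing uniformly
#'   within the action bounds
#' @export
random_policy <- function() function(state) random_action()
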