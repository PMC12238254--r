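# Shared fixtures: small cohorts, a noiseless environment config, and a
# deterministic two-state toy MDP used across the planner tests.

small_cohort <- function(n = 5L, seed = 42L) sample_cohort(cohort_config(n = n, seed = seed))

noiseless_config <- function(...) {
  env_config(noise = c(skeletal = 0, dental = 0, soft = 0,
                       functional = 0, status = 0), ...)
}

null_intervention <- function() {
  treatment_action(jaw = c(0, 0, 0), force_magnitude = 0,
                   soft_tissue_technique = "none", phase_decision = "hold",
                   interval_weeks = 6)
}

class_iii_record <- function(anb = -2.8, seed = 7L) {
  patient_record("T-III", 23, "female", "ClassIII", anb, 26, 1L,
                 record_seed = seed)
}

class_ii_record <- function(anb = 5.9, seed = 8L) {
  patient_record("T-II", 24, "male", "ClassII", anb, 24, 2L,
                 record_seed = seed)
}

# Deterministic 2-state, 2-action MDP with vector rewards. Action 1 keeps
# the current state, action 2 swaps states; state 2 pays more than state 1.
two_state_mdp <- function(gamma = 0.5) {
  P <- array(0, c(2, 2, 2))
  P[1, 1, 1] <- 1; P[1, 2, 2] <- 1
  P[2, 1, 2] <- 1; P[2, 2, 1] <- 1
  R <- array(0, c(2, 2, 4))
  base <- matrix(c(0.1, 0.6,   # state 1: stay, swap
                   1.0, 0.2),  # state 2: stay, swap
                 2, 2, byrow = TRUE)
  for (i in 1:4) R[, , i] <- base * c(1, 0.8, 1.2, 1)[i]
  finite_mdp(P, R, gamma = gamma)
}

# Random enumerable MDP with fixed seed (stochastic transitions).
random_mdp <- function(S = 8L, K = 3L, n_tasks = 4L, gamma = 0.9, seed = 1L) {
  set.seed(seed)
  P <- array(0, c(S, K, S))
  for (s in seq_len(S)) for (k in seq_len(K)) {
    p <- stats::rexp(S)^2
    P[s, k, ] <- p / sum(p)
  }
  R <- array(stats::runif(S * K * n_tasks), c(S, K, n_tasks))
  finite_mdp(P, R, gamma = gamma)
}
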