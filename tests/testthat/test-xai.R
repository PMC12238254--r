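test_that("attribution is exact for additive models and always complete", {
  set.seed(1)
  d <- 8L
  cf <- rnorm(d)
  lin <- function(M) as.numeric(M %*% cf)
  x <- rnorm(d); names(x) <- paste0("f", 1:d)
  b <- rnorm(d)
  at <- feature_attribution(lin, x, b, n_samples = 20L, seed = 3)
  expect_equal(unname(at$contributions), unname(cf * (x - b)), tolerance = 1e-10)
  expect_equal(sum(at$contributions), lin(matrix(x, 1)) - lin(matrix(b, 1)),
               tolerance = 1e-6)

  # null difference
  at0 <- feature_attribution(lin, x, x, n_samples = 8L, seed = 3)
  expect_equal(unname(at0$contributions), rep(0, d))

  # completeness for a non-additive model, and determinism under the seed
  nl <- function(M) as.numeric(sin(M[, 1] * M[, 2]) + M[, 3]^2 +
                                 exp(M[, 4] / 3))
  a1 <- feature_attribution(nl, x, b, n_samples = 64L, seed = 5)
  a2 <- feature_attribution(nl, x, b, n_samples = 64L, seed = 5)
  expect_identical(a1$contributions, a2$contributions)
  expect_lt(abs(sum(a1$contributions) - (a1$target - a1$target_baseline)),
            1e-6)
  expect_error(feature_attribution(function(M) rep(NaN, nrow(M)), x, b,
                                   n_samples = 4L), "non-finite")
})

test_that("duplicated identical features receive equal attribution", {
  f <- function(M) as.numeric(M[, 1] + M[, 2])
  x <- c(a = 2, b = 2); b0 <- c(a = 0, b = 0)
  at <- feature_attribution(f, x, b0, n_samples = 32L, seed = 1)
  expect_equal(unname(at$contributions[1]), unname(at$contributions[2]),
               tolerance = 1e-10)
})

test_that("integrated gradients satisfies completeness on a smooth model", {
  set.seed(2)
  f <- function(M) as.numeric(M[, 1]^2 + 2 * M[, 2] * M[, 3] - M[, 4])
  x <- rnorm(4); b <- rnorm(4)
  ig <- integrated_gradients(f, x, b, n_steps = 64L)
  expect_lt(abs(sum(ig$contributions) - (ig$target - ig$target_baseline)),
            1e-6)
})

test_that("surrogate recovers a planted threshold rule with high fidelity", {
  set.seed(4)
  n <- 5000L
  states <- data.frame(relapse_risk = runif(n), bone_density = runif(n),
                       harmony = runif(n, 0, 10))
  policy <- function(df) ifelse(df$relapse_risk < 0.3, "proceed", "hold")
  sur <- fit_surrogate(policy, states, max_depth = 1L, seed = 2)
  expect_false(sur$degenerate)
  expect_gte(sur$fidelity, 0.98)
  # the learned split sits within 0.02 of the planted threshold
  split_row <- sur$tree$splits
  thr <- split_row[rownames(split_row) == "relapse_risk", "index"][1]
  expect_lt(abs(thr - 0.3), 0.02)
  # fidelity is computed on held-out states, never training states
  expect_equal(sur$n_train + sur$n_test, n)
  expect_gt(sur$n_test, 0L)

  const <- fit_surrogate(function(df) rep("proceed", nrow(df)), states,
                         seed = 2)
  expect_true(const$degenerate)
  expect_equal(const$fidelity, 1.0)
  expect_equal(unique(surrogate_predict(const, states[1:5, ])), "proceed")
})

test_that("counterfactuals solve 1-D threshold problems to grid resolution", {
  f <- function(M) as.numeric(M[, 1])          # monotone in the feature
  bounds <- list(lo = 0, hi = 10)
  cf <- counterfactual_search(f, state = 2, target = list(direction = ">=",
                                                          value = 7),
                              bounds = bounds, grid_points = 101L, seed = 1)
  expect_true(cf$feasible)
  expect_equal(cf$distance, 5, tolerance = 0.1)  # grid spacing 0.1

  # degenerate target: already satisfied -> zero deltas
  cf0 <- counterfactual_search(f, state = 8, target = list(direction = ">=",
                                                           value = 7),
                               bounds = bounds)
  expect_equal(cf0$sparsity, 0L)
  expect_equal(cf0$distance, 0)

  # infeasible target reported, not thrown
  cfi <- counterfactual_search(f, state = 2, target = list(direction = ">=",
                                                           value = 99),
                               bounds = bounds)
  expect_false(cfi$feasible)
})

test_that("counterfactual distance is near brute-force optimal on 21^3 grids", {
  set.seed(9)
  grids <- lapply(1:3, function(j) seq(0, 1, length.out = 21L))
  full <- as.matrix(expand.grid(grids))
  models <- list(
    function(M) as.numeric(M %*% c(1, 2, 0.5)),
    function(M) as.numeric(M[, 1] * M[, 2] + M[, 3]),
    function(M) as.numeric(sin(3 * M[, 1]) + M[, 2]^2 + 0.5 * M[, 3])
  )
  for (mi in seq_along(models)) {
    f <- models[[mi]]
    x0 <- c(0.25, 0.25, 0.25)
    thr <- unname(stats::quantile(f(full), 0.8))
    target <- list(direction = ">=", value = thr)
    fv <- f(full)
    dist_all <- rowSums(abs(full - matrix(x0, nrow(full), 3, byrow = TRUE)))
    opt <- min(dist_all[fv >= thr])
    cf <- counterfactual_search(f, x0, target,
                                bounds = list(lo = rep(0, 3), hi = rep(1, 3)),
                                grid_points = 21L, seed = mi)
    expect_true(cf$feasible)
    expect_lte(cf$distance, 1.05 * opt + 1e-9)
  }
})

test_that("trajectory explanations partition the episode by phase", {
  env <- treatment_env(small_cohort(2), env_config(seed = 3))
  set.seed(12)
  traj <- rollout_episode(env, random_policy())
  te <- explain_trajectory(traj)
  seg <- te$segments
  # spans are disjoint and cover 1..T
  covered <- unlist(mapply(seq, seg$from_step, seg$to_step, SIMPLIFY = FALSE))
  expect_equal(covered, seq_along(traj))
  expect_true(all(diff(seg$phase) >= 0))
  expect_length(te$transitions, length(traj))

  # constructed fixture: phase 2 dominated by the aesthetic component
  mk_step <- function(phase, r) list(
    state = list(treatment_status = list(phase = phase, elapsed_months = 0)),
    action = treatment_action(), reward = r,
    next_state = list(treatment_status = list(phase = phase,
                                              elapsed_months = 1)))
  fix <- c(lapply(1:3, function(i) mk_step(1L, c(0.9, 0.1, 0.2, 0.1))),
           lapply(1:3, function(i) mk_step(2L, c(0.1, 0.9, 0.1, 0.1))))
  class(fix) <- "trajectory"
  te2 <- explain_trajectory(fix)
  expect_equal(nrow(te2$segments), 2L)
  expect_equal(te2$segments$dominant_component, c("functional", "aesthetic"))
})

test_that("reports keep rankings across audiences and honor top_k", {
  set.seed(3)
  cf <- rnorm(6)
  lin <- function(M) as.numeric(M %*% cf)
  x <- rnorm(6); names(x) <- paste0("m", 1:6)
  at <- feature_attribution(lin, x, x * 0, n_samples = 16L, seed = 1)
  r_spec <- render_report(at, "specialist", top_k = 3L)
  r_inter <- render_report(at, "interdisciplinary", top_k = 3L)
  expect_identical(r_spec$data$ranking, r_inter$data$ranking)
  expect_length(r_spec$data$ranking, 3L)
  expect_error(render_report(at, "patient"), "unknown audience")

  cf0 <- counterfactual_search(function(M) as.numeric(M[, 1]), 5,
                               list(direction = ">=", value = 1),
                               bounds = list(lo = 0, hi = 10))
  rep0 <- render_report(cf0, "specialist")
  expect_true(any(grepl("no modification needed", rep0$text)))
})
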