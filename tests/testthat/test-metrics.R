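test_that("outcome-forecast accuracy matches the formula and its edge cases", {
  expect_equal(accuracy_at(c(1, 2), c(1, 2)), 1.0)
  expect_equal(accuracy_at(90, 100), 0.9)
  expect_equal(accuracy_at(c(12, 20), c(10, 20)), 0.9)
  expect_error(accuracy_at(c(1, 2), c(1, 0)), "zero")
  expect_error(accuracy_at(c(1, 2), c(0, 1)), "'1'")
  # scale invariance under joint rescaling
  set.seed(2)
  for (i in 1:20) {
    y <- runif(5, 1, 10); yh <- y + rnorm(5)
    ce <- runif(1, 0.1, 5) * sample(c(-1, 1), 1)
    expect_equal(accuracy_at(yh, y), accuracy_at(ce * yh, ce * y))
  }
})

test_that("efficiency index and confidence score follow their formulas", {
  expect_equal(efficiency_index(1, 1, 1), 1)
  expect_equal(efficiency_index(1, 2, 1), 0.5)
  expect_equal(efficiency_index(80, 26.3, 1.0), 80 / 26.3)
  expect_equal(efficiency_index(80, 26.3), 3.0418, tolerance = 1e-4)
  expect_error(efficiency_index(1, 0), "> 0")

  expect_equal(confidence_score(1, 1, 1), 1)
  expect_equal(confidence_score(1, 0, 0, alpha = 1, beta = 0, gamma = 0), 1)
  expect_equal(confidence_score(0.8, 0.6, 0.9), 0.7667, tolerance = 1e-4)
  expect_error(confidence_score(1.2, 0, 0), "\\[0, 1\\]")
  expect_error(confidence_score(1, 1, 1, alpha = 1, beta = 1, gamma = 1),
               "sum to 1")
})

test_that("chronological partition reproduces the published split sizes", {
  mk <- function(n) lapply(seq_len(n), function(i)
    list(id = i, enrollment_index = n - i + 1L))  # reversed order on purpose
  sp <- partition_chronological(mk(347))
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 243L, validation = 52L, test = 52L))
  sp10 <- partition_chronological(mk(10))
  expect_equal(vapply(sp10, length, integer(1)),
               c(train = 7L, validation = 2L, test = 1L))
  # earliest keys go to training; partition is loss-free
  keys_tr <- vapply(sp10$train, function(r) r$enrollment_index, numeric(1))
  expect_equal(sort(keys_tr), as.numeric(1:7))
  all_keys <- sort(unname(unlist(lapply(unlist(sp10, recursive = FALSE),
                                        `[[`, "enrollment_index"))))
  expect_equal(all_keys, 1:10)
  empty <- partition_chronological(list())
  expect_equal(vapply(empty, length, integer(1)),
               c(train = 0L, validation = 0L, test = 0L))
})

test_that("paired permutation p-values are valid and null-uniform", {
  set.seed(11)
  x <- rnorm(30, 1); y <- rnorm(30)
  p <- paired_permutation_test(x, y, n_perm = 499, alternative = "greater",
                               seed = 1)$p_value
  expect_lt(p, 0.01)
  expect_gte(p, 0)

  # null uniformity: KS test over 200 null simulations at alpha = 0.01
  pvals <- vapply(seq_len(200L), function(i) {
    a <- rnorm(15); b <- rnorm(15)
    paired_permutation_test(a, b, n_perm = 199, seed = i)$p_value
  }, numeric(1))
  expect_true(all(pvals >= 0 & pvals <= 1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("policy comparison detects dominance and is null for self-comparison", {
  ch <- small_cohort(4)
  env <- treatment_env(ch, env_config(seed = 2))
  clamp01 <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  corrective <- function(state) {
    gap <- 2 - state$skeletal$ceph[["ANB"]]
    treatment_action(jaw = c(clamp01(gap / 0.5, -15, 15), 0, 0),
                     force_magnitude = 150, phase_decision = "hold",
                     interval_weeks = 7)
  }
  # planted inferior policy: always operates away from the target with
  # maximal movement and excessive force
  harmful <- function(state) {
    gap <- 2 - state$skeletal$ceph[["ANB"]]
    treatment_action(jaw = c(-sign(gap) * 15, 8, 6),
                     force_magnitude = 300,
                     soft_tissue_technique = "reduction",
                     phase_decision = "hold", interval_weeks = 4)
  }
  cmp <- compare_policies(env, list(A = corrective, B = harmful),
                          n_episodes = 30, seed = 5)
  expect_equal(nrow(cmp$summary), 2L)
  su <- cmp$summary
  expect_gt(su$return_mean[su$policy == "A"], su$return_mean[su$policy == "B"])
  pw <- cmp$pairwise
  expect_true(all(pw$p_bonferroni[pw$metric == "return_scalar"] < 0.01))
  expect_gt(pw$improvement_pct[pw$metric == "tpqs"], 0)

  cmp_self <- compare_policies(env, list(A = corrective, A2 = corrective),
                               n_episodes = 10, seed = 5)
  expect_equal(cmp_self$pairwise$improvement_pct,
               c(0, 0), tolerance = 1e-9)
  expect_true(all(cmp_self$pairwise$p_raw > 0.9))
})
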