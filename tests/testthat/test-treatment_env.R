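test_that("action space descriptors match the published bounds", {
  expect_equal(action_space_spec("jaw")$sagittal_mm, c(-15, 15))
  expect_equal(action_space_spec("jaw")$vertical_mm, c(-10, 10))
  expect_equal(action_space_spec("jaw")$transverse_mm, c(-8, 8))
  expect_equal(action_space_spec("dental")$force_magnitude_g, c(50, 300))
  expect_equal(action_space_spec("sequencing")$interval_weeks, c(4, 8))
  expect_setequal(action_space_spec("sequencing")$phase_decision,
                  c("proceed", "hold", "modify"))
  expect_error(action_space_spec("nonsense"), "unknown task type")
})

test_that("reset returns a valid pre-treatment state", {
  cfg <- noiseless_config()
  st <- env_reset(class_iii_record(), cfg)
  expect_equal(st$treatment_status$phase, 1L)
  expect_equal(st$treatment_status$elapsed_months, 0)
  expect_lt(st$skeletal$ceph[["ANB"]], 0)
  expect_identical(st, env_reset(class_iii_record(), cfg))
})

test_that("null intervention leaves morphology fixed, advances healing", {
  cfg <- noiseless_config()
  st <- env_reset(class_iii_record(), cfg)
  res <- simulate_response(st, null_intervention(), 1.2, cfg)
  s2 <- res$state
  expect_identical(s2$skeletal$ceph, st$skeletal$ceph)
  expect_identical(s2$skeletal$landmarks, st$skeletal$landmarks)
  expect_identical(s2$dental$teeth, st$dental$teeth)
  expect_identical(s2$soft_tissue$facial_harmony, st$soft_tissue$facial_harmony)
  expect_identical(s2$functional, st$functional)
  expect_equal(s2$treatment_status$elapsed_months, 1.2)
  expect_gt(s2$treatment_status$tissue_adaptation,
            st$treatment_status$tissue_adaptation)
})

test_that("corrective sagittal surgery raises a Class III ANB", {
  cfg <- noiseless_config()
  st <- env_reset(class_iii_record(-2.8), cfg)
  a <- treatment_action(jaw = c(15, 0, 0), force_magnitude = 150,
                        phase_decision = "hold")
  s2 <- simulate_response(st, a, 1.4, cfg)$state
  expect_gt(s2$skeletal$ceph[["ANB"]], st$skeletal$ceph[["ANB"]])
  # never overshoots the ideal relation
  expect_lte(s2$skeletal$ceph[["ANB"]], cfg$ideal_anb + 1e-9)
})

test_that("saturating response: staged movement beats one large move, which costs more relapse", {
  cfg <- noiseless_config()
  u0 <- cfg$jaw_sat_mm
  eff <- function(d) u0 * (1 - exp(-abs(d) / u0)) * sign(d)
  # frozen from the documented response curve 8 * (1 - exp(-d/8))
  expect_equal(eff(5), 3.7179100, tolerance = 1e-6)
  expect_equal(eff(10), 5.7079616, tolerance = 1e-6)

  st <- env_reset(class_iii_record(-6), cfg)
  a5 <- treatment_action(jaw = c(5, 0, 0), force_magnitude = 0,
                         phase_decision = "hold")
  a10 <- treatment_action(jaw = c(10, 0, 0), force_magnitude = 0,
                          phase_decision = "hold")
  one <- simulate_response(st, a10, 1.4, cfg)
  two1 <- simulate_response(st, a5, 1.4, cfg)
  two2 <- simulate_response(two1$state, a5, 1.4, cfg)
  anb_one <- one$state$skeletal$ceph[["ANB"]]
  anb_two <- two2$state$skeletal$ceph[["ANB"]]
  # both land within the documented saturation range; staged achieves more
  expect_equal(anb_one, st$skeletal$ceph[["ANB"]] + 0.5 * eff(10),
               tolerance = 1e-9)
  expect_gt(anb_two, anb_one)
  # per-step relapse increment larger for the single 10 mm move
  d_one <- one$state$treatment_status$relapse_risk -
    st$treatment_status$relapse_risk
  d_two <- two1$state$treatment_status$relapse_risk -
    st$treatment_status$relapse_risk
  expect_gt(d_one, d_two)
})

test_that("monotone correction: repeated maximal action drives ANB to the target", {
  cfg <- noiseless_config()
  st <- env_reset(class_iii_record(-6), cfg)
  a <- treatment_action(jaw = c(15, 0, 0), force_magnitude = 0,
                        phase_decision = "hold")
  prev <- st$skeletal$ceph[["ANB"]]
  for (k in 1:6) {
    st <- simulate_response(st, a, 1.4, cfg)$state
    cur <- st$skeletal$ceph[["ANB"]]
    expect_gte(cur, prev)
    expect_lte(cur, cfg$ideal_anb + 1e-9)
    prev <- cur
  }
  expect_equal(prev, cfg$ideal_anb, tolerance = 1e-6)
})

test_that("step clips out-of-bounds actions and records the clip", {
  cfg <- noiseless_config()
  st <- env_reset(class_iii_record(), cfg)
  a <- treatment_action(jaw = c(20, 0, 0), force_magnitude = 150,
                        phase_decision = "hold", validate = FALSE)
  out <- env_step(st, a, cfg)
  expect_true("jaw.sagittal" %in% out$info$clips)
  # executed movement equals the clipped 15 mm command
  expect_equal(out$info$eff_jaw[1],
               cfg$jaw_sat_mm * (1 - exp(-15 / cfg$jaw_sat_mm)),
               tolerance = 1e-9)
})

test_that("with zero noise a step is exactly the deterministic response plus reward", {
  cfg <- noiseless_config()
  st <- env_reset(class_ii_record(), cfg)
  a <- treatment_action(jaw = c(-6, 0, 0), force_magnitude = 120,
                        phase_decision = "hold", interval_weeks = 5)
  out <- env_step(st, a, cfg)
  ref <- simulate_response(st, a, 5 * 12 / 52, cfg)
  expect_identical(out$next_state$skeletal, ref$state$skeletal)
  expect_identical(out$next_state$functional, ref$state$functional)
  expect_equal(unclass(out$reward),
               unclass(reward_components(st, a, ref$state, cfg$reward)))
})

test_that("episodes are deterministic given seeds and states stay valid", {
  ch <- small_cohort(3)
  cfg <- env_config(seed = 4)
  env <- treatment_env(ch, cfg)
  set.seed(99)
  t1 <- rollout_episode(env, random_policy(), record_index = 1L)
  set.seed(99)
  env2 <- treatment_env(ch, cfg)
  t2 <- rollout_episode(env2, random_policy(), record_index = 1L)
  expect_equal(length(t1), length(t2))
  expect_identical(t1[[length(t1)]]$next_state, t2[[length(t2)]]$next_state)
  # state validity closure along the whole trajectory
  for (tr in t1) expect_equal(nrow(validate_state(tr$next_state)), 0L)
  expect_error(env_step(t1[[length(t1)]]$next_state,
                        null_intervention(), cfg), "finished")
})

test_that("per-step state changes are bounded by gain x action plus noise", {
  cfg <- env_config(seed = 8)
  st0 <- env_reset(class_iii_record(-6), cfg)
  set.seed(8)
  max_anb_gain <- cfg$anb_gain_deg_per_mm * cfg$jaw_sat_mm  # saturated bound
  anb_bound <- max_anb_gain + 3 * cfg$noise[["skeletal"]] + 1e-9
  harm_bound <- cfg$harmony_rate * 10 * (max_anb_gain / 10) + 0.25 +
    3 * cfg$noise[["soft"]] + 1e-9
  viol <- 0L
  for (i in 1:1000) {
    out <- env_step(st0, random_action(), cfg)
    d_anb <- abs(out$next_state$skeletal$ceph[["ANB"]] -
                   st0$skeletal$ceph[["ANB"]])
    d_harm <- abs(out$next_state$soft_tissue$facial_harmony -
                    st0$soft_tissue$facial_harmony)
    if (d_anb > anb_bound || d_harm > harm_bound) viol <- viol + 1L
  }
  expect_equal(viol, 0L)
})

test_that("trajectory export writes one JSON line per step", {
  ch <- small_cohort(2)
  env <- treatment_env(ch, env_config())
  set.seed(3)
  traj <- rollout_episode(env, random_policy())
  f <- tempfile(fileext = ".jsonl")
  write_trajectory(traj, f)
  lines <- readLines(f)
  expect_length(lines, length(traj))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("state", "action", "reward", "done") %in% names(rec)))
})
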