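# Treatment MDP environment: a first-order saturating linear-response model
# per state block (gain x action with exponential saturation and additive
# Gaussian perturbations). The response map implements
#   Response(t) = f(initial state, intervention parameters, tissue
#                   properties, t)
# as the package's biomechanical proxy; none of the coefficients are
# published values, all live in env_config() with documented defaults.

#' Environment configuration
#'
#' @param horizon_months episode horizon in months (default matches the
#'   26.3-month mean treatment duration)
#' @param max_steps hard cap on steps per episode
#' @param gamma discount factor in (0, 1]
#' @param ideal_anb target sagittal relation, degrees
#' @param jaw_sat_mm saturation scale of surgical movement response: a
#'   commanded per-axis displacement d yields `jaw_sat_mm * (1 -
#'   exp(-|d|/jaw_sat_mm))` mm of effective movement (diminishing returns)
#' @param anb_gain_deg_per_mm cephalometric response to effective sagittal
#'   movement, degrees per mm
#' @param force_scale_g force-response scale: alignment efficacy is
#'   `1 - exp(-F/force_scale_g)`, saturating with diminishing returns above
#'   the scale
#' @param force_safe_g forces above this threshold progressively stress the
#'   TMJ
#' @param align_rate per-step fractional reduction of dental misalignment at
#'   full force efficacy
#' @param func_rate fraction of the morphology-implied functional-score
#'   change realized per step
#' @param harmony_rate fraction of the skeletal-correction-implied harmony
#'   change realized per step (soft tissue follows a fraction of skeletal
#'   correction)
#' @param relapse_gain relapse-risk increment per unit normalized movement
#' @param heal_rate relapse-risk decay per month at full tissue adaptation
#' @param adapt_rate tissue-adaptation gain per month of quiescence
#' @param bone_rate bone-density recovery per month
#' @param relapse_gate,bone_gate stability gates a `proceed` decision must
#'   pass for a phase transition
#' @param noise named per-block Gaussian noise scales (`skeletal` in deg,
#'   `dental` in deg, `soft` on the 0-10 harmony scale, `functional` and
#'   `status` on 0-1 scales); all zero gives the deterministic core
#' @param reward a [reward_config()]
#' @param seed integer seed for environment noise
#' @return an `env_config` list
#' @export
env_config <- function(horizon_months = 26.3, max_steps = 28L, gamma = 0.99,
                       ideal_anb = 2.0,
                       jaw_sat_mm = 8, anb_gain_deg_per_mm = 0.5,
                       force_scale_g = 150, force_safe_g = 250,
                       align_rate = 0.25, func_rate = 0.9,
                       harmony_rate = 0.8,
                       relapse_gain = 0.30, heal_rate = 0.25,
                       adapt_rate = 0.08, bone_rate = 0.02,
                       relapse_gate = 0.40, bone_gate = 0.50,
                       noise = c(skeletal = 0.05, dental = 0.2, soft = 0.05,
                                 functional = 0.01, status = 0.01),
                       reward = reward_config(), seed = 1L) {
  if (!is_scalar_num(horizon_months) || horizon_months <= 0)
    stop_config("horizon_months", "must be > 0")
  if (max_steps < 1) stop_config("max_steps", "must be >= 1")
  if (!is_scalar_num(gamma) || gamma <= 0 || gamma > 1)
    stop_config("gamma", "must lie in (0, 1]")
  if (any(noise < 0)) stop_config("noise", "noise scales must be >= 0")
  structure(as.list(environment()), class = "env_config")
}

# morphology-implied potentials in [0, 1]; the functional block relaxes by
# func_rate times the change in these potentials, so a null intervention
# leaves the functional block exactly unchanged
potentials <- function(state, cfg) {
  gap <- abs(state$skeletal$ceph[["ANB"]] - cfg$ideal_anb)
  mis <- dental_misalignment(state)
  list(occ = clamp(1 - gap / 8 - mis / 15, 0, 1),
       tmj = clamp(1 - gap / 12, 0, 1),
       resp = clamp(1 - gap / 14, 0, 1),
       harmony = clamp(1 - gap / 10, 0, 1))
}

#' Reset the treatment environment for a patient
#'
#' Returns the pre-treatment state: phase 1, zero elapsed months, sampled
#' deterministically from the record's substream seed.
#'
#' @param record a [patient_record()]
#' @param config an [env_config()]
#' @param schema a [measurement_schema()]
#' @return a valid `patient_state`
#' @export
env_reset <- function(record, config = env_config(),
                      schema = measurement_schema()) {
  if (!inherits(config, "env_config"))
    stop_config("config", "must be built by env_config()")
  sample_patient_state(record, schema, seed = record$record_seed)
}

#' Deterministic biomechanical response over one interval
#'
#' The noiseless core of the transition model. Skeletal blocks move by the
#' commanded jaw vector attenuated by a saturating response curve;
#' corrective cephalometric change saturates at the ideal sagittal relation
#' (overshoot past the target is not produced by the model, movement away
#' from it is unattenuated). Dental angulations decay toward alignment at a
#' rate proportional to the saturating force efficacy; facial harmony
#' follows a configured fraction of the skeletal correction; relapse risk
#' rises with per-step movement magnitude and decays with tissue
#' adaptation; adaptation and bone density recover with quiescent time.
#'
#' @param state a valid `patient_state`
#' @param action an in-bounds `treatment_action` (callers clip first); a
#'   `force_magnitude` of 0 denotes no active appliance
#' @param dt_months interval length in months
#' @param params an [env_config()]
#' @return list with `state` (next `patient_state`), `eff_jaw` (effective
#'   movement, mm), `anb_applied` (deg), `movement` (normalized magnitude),
#'   `phase_complete` (flag)
#' @export
simulate_response <- function(state, action, dt_months, params = env_config()) {
  v <- action_violations(action)
  if (length(v)) stop("contract violation, action out of bounds: ",
                      paste(v, collapse = "; "), call. = FALSE)
  cfg <- params
  s <- state
  pot0 <- potentials(s, cfg)

  # --- skeletal response: saturating per-axis effective movement ---------
  d <- action$jaw
  u0 <- cfg$jaw_sat_mm
  eff <- sign(d) * u0 * (1 - exp(-abs(d) / u0))
  anb <- s$skeletal$ceph[["ANB"]]
  d_anb_raw <- cfg$anb_gain_deg_per_mm * eff[1]
  gap <- cfg$ideal_anb - anb
  d_anb <- if (sign(d_anb_raw) == sign(gap) && gap != 0)
    sign(gap) * min(abs(d_anb_raw), abs(gap)) else if (gap == 0) 0 else d_anb_raw
  applied_frac <- if (abs(d_anb_raw) > 1e-12) d_anb / d_anb_raw else 0
  s$skeletal$ceph[["ANB"]] <- anb + d_anb
  s$skeletal$ceph[["SNB"]] <- s$skeletal$ceph[["SNA"]] - s$skeletal$ceph[["ANB"]]
  mand <- s$skeletal$landmarks[, "vertical"] < 0
  s$skeletal$landmarks[mand, "sagittal"] <-
    s$skeletal$landmarks[mand, "sagittal"] + eff[1] * applied_frac
  s$skeletal$landmarks[mand, "vertical"] <-
    s$skeletal$landmarks[mand, "vertical"] + eff[2]
  s$skeletal$landmarks[mand, "transverse"] <-
    s$skeletal$landmarks[mand, "transverse"] + eff[3]

  # --- dental response: force-driven alignment with diminishing returns --
  Fm <- action$force_magnitude
  g <- if (Fm <= 0) 0 else 1 - exp(-Fm / cfg$force_scale_g)
  appl_factor <- c(brackets = 1.0, wires = 0.9, elastics = 0.7)[action$appliance]
  dir_quality <- 0.6 + 0.4 * abs(action$force_direction[1])
  decay <- clamp(cfg$align_rate * g * appl_factor * dir_quality *
                   dt_months / 1.4, 0, 0.9)
  s$dental$teeth[, c("tip", "torque", "rotation")] <-
    s$dental$teeth[, c("tip", "torque", "rotation")] * (1 - decay)

  # --- potentials after morphology change --------------------------------
  pot1 <- potentials(s, cfg)
  s$functional$occlusal_function <- clamp(
    s$functional$occlusal_function + cfg$func_rate * (pot1$occ - pot0$occ), 0, 1)
  tmj_stress <- 0.05 * max(0, Fm - cfg$force_safe_g) / 50 * dt_months / 1.4
  s$functional$tmj_health <- clamp(
    s$functional$tmj_health + cfg$func_rate * (pot1$tmj - pot0$tmj) - tmj_stress,
    0, 1)
  s$functional$respiratory <- clamp(
    s$functional$respiratory + cfg$func_rate * (pot1$resp - pot0$resp), 0, 1)

  # --- soft tissue follows a fraction of skeletal correction -------------
  d_harm <- cfg$harmony_rate * (pot1$harmony - pot0$harmony) * 10
  tech_bonus <- switch(action$soft_tissue_technique,
                       VY_advancement = 0.25, reduction = 0.10, none = 0) *
    (1 - s$soft_tissue$facial_harmony / 10)
  s$soft_tissue$facial_harmony <-
    clamp(s$soft_tissue$facial_harmony + d_harm + tech_bonus, 0, 10)

  # --- healing indicators ------------------------------------------------
  movement <- sqrt(sum(eff^2)) / 20 + 0.2 * g
  if (action$soft_tissue_technique != "none") movement <- movement + 0.05
  dt_norm <- dt_months / 1.4
  st <- s$treatment_status
  st$relapse_risk <- clamp(st$relapse_risk + cfg$relapse_gain * movement -
                             cfg$heal_rate * st$tissue_adaptation * dt_norm, 0, 1)
  st$tissue_adaptation <- clamp(
    st$tissue_adaptation + cfg$adapt_rate * dt_norm * (1 - clamp(movement, 0, 1)),
    0, 1)
  st$bone_density <- clamp(st$bone_density + cfg$bone_rate * dt_norm -
                             0.1 * movement, 0.05, 1)
  if (action$phase_decision == "modify")
    st$tissue_adaptation <- clamp(st$tissue_adaptation - 0.05, 0, 1)

  # --- phase progression through stability gates -------------------------
  phase_complete <- FALSE
  if (action$phase_decision == "proceed" &&
      st$relapse_risk < cfg$relapse_gate && st$bone_density > cfg$bone_gate) {
    if (st$phase >= 4L) phase_complete <- TRUE
    else st$phase <- st$phase + 1L
  }
  st$elapsed_months <- st$elapsed_months + dt_months
  s$treatment_status <- st

  list(state = s, eff_jaw = eff, anb_applied = d_anb,
       movement = movement, phase_complete = phase_complete)
}

#' One environment step
#'
#' Clips the action into bounds (recording which fields were clipped),
#' applies [simulate_response()] over `interval_weeks * 12/52` months, adds
#' seeded Gaussian perturbations scaled by the configured per-block noise,
#' computes the reward vector, and flags episode termination (phase 4
#' completed through the stability gates, or the elapsed-months horizon
#' reached).
#'
#' @param state current `patient_state` (not yet terminal)
#' @param action requested `treatment_action` (may exceed bounds; clipped)
#' @param config an [env_config()]
#' @return a `step_outcome` list: `next_state`, `reward`
#'   (a `reward_vector`), `done`, `info` (clips, effective movement,
#'   phase-completion flag)
#' @export
env_step <- function(state, action, config = env_config()) {
  if (isTRUE(state$treatment_status$completed) ||
      state$treatment_status$elapsed_months >= config$horizon_months)
    stop("cannot step a finished episode", call. = FALSE)
  cl <- clip_action(action)
  a <- cl$action
  dt <- a$interval_weeks * 12 / 52
  res <- simulate_response(state, a, dt, config)
  s2 <- res$state

  ns <- config$noise
  if (any(ns > 0)) {
    if (ns[["skeletal"]] > 0) {
      s2$skeletal$ceph[["ANB"]] <- s2$skeletal$ceph[["ANB"]] +
        stats::rnorm(1, 0, ns[["skeletal"]])
      s2$skeletal$ceph[["SNB"]] <- s2$skeletal$ceph[["SNA"]] -
        s2$skeletal$ceph[["ANB"]]
    }
    if (ns[["dental"]] > 0)
      s2$dental$teeth[, c("tip", "torque", "rotation")] <-
        s2$dental$teeth[, c("tip", "torque", "rotation")] +
        matrix(stats::rnorm(3 * N_TEETH, 0, ns[["dental"]]), ncol = 3)
    if (ns[["soft"]] > 0)
      s2$soft_tissue$facial_harmony <-
        clamp(s2$soft_tissue$facial_harmony + stats::rnorm(1, 0, ns[["soft"]]),
              0, 10)
    if (ns[["functional"]] > 0) {
      for (f in c("occlusal_function", "tmj_health", "respiratory"))
        s2$functional[[f]] <- clamp(s2$functional[[f]] +
                                      stats::rnorm(1, 0, ns[["functional"]]), 0, 1)
    }
    if (ns[["status"]] > 0) {
      s2$treatment_status$relapse_risk <-
        clamp(s2$treatment_status$relapse_risk +
                stats::rnorm(1, 0, ns[["status"]]), 0, 1)
    }
  }

  r <- reward_components(state, a, s2, config$reward)
  done <- res$phase_complete ||
    s2$treatment_status$elapsed_months >= config$horizon_months
  if (res$phase_complete) s2$treatment_status$completed <- TRUE
  structure(list(
    next_state = s2, reward = r, done = done,
    info = list(clips = cl$clips, eff_jaw = res$eff_jaw,
                anb_applied = res$anb_applied, movement = res$movement,
                phase_complete = res$phase_complete)
  ), class = "step_outcome")
}

#' Treatment environment object
#'
#' Wraps a patient cohort and an [env_config()] into a stateful episodic
#' environment for the planner: `$reset(i)` starts an episode on cohort
#' member `i` (cycling if omitted), `$step(action)` advances it.
#'
#' @param records list of [patient_record()]
#' @param config an [env_config()]
#' @return an environment with fields `state`, `done`, `steps`, methods
#'   `reset(i)`, `step(action)`, and the config under `config`
#' @export
treatment_env <- function(records, config = env_config()) {
  stopifnot(length(records) >= 1L)
  e <- new.env(parent = emptyenv())
  e$records <- records
  e$config <- config
  e$cursor <- 0L
  e$state <- NULL
  e$done <- TRUE
  e$steps <- 0L
  e$reset <- function(i = NULL) {
    if (is.null(i)) {
      e$cursor <- (e$cursor %% length(e$records)) + 1L
      i <- e$cursor
    }
    e$state <- env_reset(e$records[[i]], e$config)
    e$done <- FALSE
    e$steps <- 0L
    e$state
  }
  e$step <- function(action) {
    out <- env_step(e$state, action, e$config)
    e$steps <- e$steps + 1L
    if (e$steps >= e$config$max_steps) out$done <- TRUE
    e$state <- out$next_state
    e$done <- out$done
    out
  }
  class(e) <- c("treatment_env", "environment")
  e
}

#' Roll out a policy for one episode
#'
#' @param env a [treatment_env()]
#' @param policy a function `state -> treatment_action`
#' @param record_index cohort member to treat (default: cycle)
#' @return a `trajectory`: list of per-step lists `(state, action, reward,
#'   next_state, done, info)`
#' @export
rollout_episode <- function(env, policy, record_index = NULL) {
  s <- env$reset(record_index)
  traj <- list()
  repeat {
    a <- policy(s)
    out <- env$step(a)
    traj[[length(traj) + 1L]] <- list(state = s, action = a,
                                      reward = out$reward,
                                      next_state = out$next_state,
                                      done = out$done, info = out$info)
    s <- out$next_state
    if (out$done) break
  }
  class(traj) <- "trajectory"
  traj
}

#' Export a trajectory as JSON-lines
#'
#' One line per step carrying a state digest (cephalometrics, harmony,
#' functional scores, status block), the action, the reward vector and step
#' diagnostics.
#'
#' @param traj a trajectory from [rollout_episode()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path) {
  digest_state <- function(s) list(
    ANB = s$skeletal$ceph[["ANB"]], harmony = s$soft_tissue$facial_harmony,
    occ = s$functional$occlusal_function, tmj = s$functional$tmj_health,
    resp = s$functional$respiratory, phase = s$treatment_status$phase,
    relapse = s$treatment_status$relapse_risk,
    elapsed_months = s$treatment_status$elapsed_months)
  lines <- vapply(traj, function(tr) {
    jsonlite::toJSON(list(state = digest_state(tr$state),
                          action = unclass(tr$action),
                          reward = as.list(unclass(tr$reward)),
                          done = tr$done, clips = tr$info$clips),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
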