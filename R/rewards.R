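# Multi-objective reward structure: four task rewards (functional,
# aesthetic, efficiency, stability), their weighted scalarization, and the
# composite Treatment Plan Quality Score with AHP-derived weights.

#' Task weights over the four treatment objectives
#'
#' Defaults are the AHP-derived quality-score weights (function 0.30,
#' aesthetics 0.25, efficiency 0.25, stability 0.20); any non-negative
#' weights summing to one are accepted.
#'
#' @param functional,aesthetic,efficiency,stability non-negative weights
#' @return class `task_weights`, a named numeric vector summing to 1
#' @export
task_weights <- function(functional = 0.30, aesthetic = 0.25,
                         efficiency = 0.25, stability = 0.20) {
  w <- c(functional = functional, aesthetic = aesthetic,
         efficiency = efficiency, stability = stability)
  if (any(w < 0)) stop("task weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop(sprintf("task weights must sum to 1 (got %.12f)", sum(w)),
         call. = FALSE)
  structure(w, class = c("task_weights", "numeric"))
}

#' Reward-shaping coefficients
#'
#' @param func_step_scale reference per-step improvement of the functional
#'   scores that earns full functional reward (fraction of the 0-1 scale)
#' @param profile_weight weight of the profile-balance improvement inside
#'   the aesthetic reward (harmony improvement has weight 1 on its 0-10
#'   scale)
#' @param eff_time_weight,eff_burden_weight split of the efficiency penalty
#'   between elapsed chair time and appointment burden (shorter visit
#'   intervals mean more appointments per month)
#' @return list of coefficients
#' @export
reward_config <- function(func_step_scale = 0.10, profile_weight = 0.5,
                          eff_time_weight = 0.3, eff_burden_weight = 0.7) {
  list(func_step_scale = func_step_scale, profile_weight = profile_weight,
       eff_time_weight = eff_time_weight, eff_burden_weight = eff_burden_weight)
}

#' Reward vector for one treatment transition
#'
#' * `functional`: mean normalized improvement of occlusal function, TMJ
#'   health and respiratory score over the step.
#' * `aesthetic`: normalized improvement of facial harmony (0-10 scale)
#'   plus a weighted profile-balance improvement.
#' * `efficiency`: one minus the normalized time cost of the step and the
#'   appointment burden implied by the visit interval.
#' * `stability`: one minus the post-step relapse risk, modulated by tissue
#'   adaptation.
#'
#' Each component is clamped to \[0, 1\].
#'
#' @param s,s_next `patient_state` before and after the step
#' @param a the executed `treatment_action`
#' @param config a [reward_config()]
#' @return class `reward_vector`: named numeric (functional, aesthetic,
#'   efficiency, stability), each in \[0, 1\]
#' @export
reward_components <- function(s, a, s_next, config = reward_config()) {
  d_func <- mean(c(
    s_next$functional$occlusal_function - s$functional$occlusal_function,
    s_next$functional$tmj_health - s$functional$tmj_health,
    s_next$functional$respiratory - s$functional$respiratory))
  r_func <- clamp(d_func / config$func_step_scale, 0, 1)

  d_harm <- (s_next$soft_tissue$facial_harmony - s$soft_tissue$facial_harmony) / 10
  d_prof <- profile_balance(s_next) - profile_balance(s)
  r_aes <- clamp(d_harm + config$profile_weight * d_prof, 0, 1)

  dt <- a$interval_weeks * 12 / 52
  dt_min <- 4 * 12 / 52; dt_max <- 8 * 12 / 52
  r_eff <- clamp(1 - config$eff_time_weight * dt / dt_max -
                   config$eff_burden_weight * dt_min / dt, 0, 1)

  r_stab <- clamp((1 - s_next$treatment_status$relapse_risk) *
                    (0.5 + 0.5 * s_next$treatment_status$tissue_adaptation), 0, 1)
  if (s_next$treatment_status$relapse_risk >= 1) r_stab <- 0

  structure(c(functional = r_func, aesthetic = r_aes,
              efficiency = r_eff, stability = r_stab),
            class = c("reward_vector", "numeric"))
}

#' Scalarize a reward vector
#'
#' @param r length-4 reward vector, components in \[0, 1\]
#' @param w a [task_weights()]
#' @return the weighted sum, in \[0, 1\]
#' @export
aggregate_reward <- function(r, w = task_weights()) {
  if (length(r) != 4L) stop("reward vector must have 4 components", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must lie on the simplex", call. = FALSE)
  sum(as.numeric(w) * as.numeric(r))
}

#' Treatment Plan Quality Score (TPQS)
#'
#' Composite plan-quality score over four components each rated on 0-25
#' points: occlusal function, aesthetic improvement, biomechanical
#' efficiency and stability prediction, aggregated with the AHP weights
#' (0.30/0.25/0.25/0.20). The weighted 0-25 aggregate is mapped onto the
#' reported 0-100 scale by the factor 4, which preserves all relative
#' comparisons.
#'
#' @param q named or positional numeric of the four quality components, each
#'   in \[0, 25\] points (order: function, aesthetic, efficiency, stability)
#' @param w a [task_weights()]
#' @return score on the 0-100 scale, monotone non-decreasing in every
#'   component
#' @examples
#' compute_tpqs(c(20, 15, 10, 5))  # 53
#' @export
compute_tpqs <- function(q, w = task_weights()) {
  q <- as.numeric(q)
  if (length(q) != 4L) stop("TPQS needs 4 quality components", call. = FALSE)
  if (any(q < -1e-12 | q > 25 + 1e-12))
    stop("TPQS components must lie in [0, 25] points", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must lie on the simplex", call. = FALSE)
  4 * sum(as.numeric(w) * q)
}

#' Relative improvement of a score over a reference, in percent
#'
#' @param new,ref scores; `ref` must be positive
#' @return `100 * (new - ref) / ref`, rounded to one decimal
#'   (half away from zero), the reporting convention for improvement figures
#' @examples
#' relative_improvement(87.3, 72.8)  # 19.9
#' @export
relative_improvement <- function(new, ref) {
  if (!is_scalar_num(ref) || ref <= 0)
    stop("reference score must be > 0", call. = FALSE)
  round_half_away(100 * (new - ref) / ref, 1)
}

#' Percent time reduction relative to a reference duration
#'
#' @param ref_minutes,new_minutes durations; `ref_minutes` must be positive
#' @return `100 * (ref - new) / ref`, one-decimal reporting
#' @examples
#' time_reduction(47.6, 12.4)  # 73.9
#' @export
time_reduction <- function(ref_minutes, new_minutes) {
  if (!is_scalar_num(ref_minutes) || ref_minutes <= 0)
    stop("reference duration must be > 0", call. = FALSE)
  round_half_away(100 * (ref_minutes - new_minutes) / ref_minutes, 1)
}

#' Map a final treatment state to TPQS quality components
#'
#' Computed-outcome convention for the four 0-25 point components:
#' function = 25 x mean functional score; aesthetics = 25 x mean of
#' harmony/10 and profile balance; efficiency = 25 x fraction of the
#' planning horizon saved; stability = 25 x (1 - relapse risk) modulated by
#' tissue adaptation.
#'
#' @param state final `patient_state` of an episode
#' @param horizon_months planning horizon used to normalize elapsed time
#' @return numeric length-4 vector of components in \[0, 25\]
#' @export
tpqs_input_from_state <- function(state, horizon_months = 26.3) {
  f <- state$functional
  q_fun <- 25 * mean(c(f$occlusal_function, f$tmj_health, f$respiratory))
  q_aes <- 25 * mean(c(state$soft_tissue$facial_harmony / 10,
                       profile_balance(state)))
  frac_used <- clamp(state$treatment_status$elapsed_months / horizon_months, 0, 1)
  q_eff <- 25 * (1 - 0.6 * frac_used)
  q_stab <- 25 * clamp((1 - state$treatment_status$relapse_risk) *
                         (0.5 + 0.5 * state$treatment_status$tissue_adaptation),
                       0, 1)
  clamp(c(q_fun, q_aes, q_eff, q_stab), 0, 25)
}
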