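# Hybrid treatment action: continuous surgical/orthodontic magnitudes plus
# categorical technique and sequencing choices.

APPLIANCES <- c("brackets", "wires", "elastics")
SOFT_TECHNIQUES <- c("VY_advancement", "reduction", "none")
TIMINGS <- c("simultaneous", "staged")
PHASE_DECISIONS <- c("proceed", "hold", "modify")

#' Numeric bounds and vocabularies of the action space
#'
#' Returns the bounds descriptor for one treatment task type: surgical jaw
#' movement vectors (sagittal +/-15 mm, vertical +/-10 mm, transverse
#' +/-8 mm), dental force systems (50-300 g with 3D unit direction and
#' appliance choice), soft-tissue technique selection, or treatment
#' sequencing (proceed/hold/modify with 4-8 week visit intervals).
#'
#' @param task_type one of `"jaw"`, `"dental"`, `"soft_tissue"`,
#'   `"sequencing"`
#' @return a list of numeric ranges (with units) and categorical levels
#' @examples
#' action_space_spec("jaw")$sagittal_mm  # c(-15, 15)
#' @export
action_space_spec <- function(task_type) {
  specs <- list(
    jaw = list(sagittal_mm = c(-15, 15), vertical_mm = c(-10, 10),
               transverse_mm = c(-8, 8)),
    dental = list(force_magnitude_g = c(50, 300),
                  force_direction = "unit 3-vector",
                  appliance = APPLIANCES),
    soft_tissue = list(technique = SOFT_TECHNIQUES, timing = TIMINGS),
    sequencing = list(phase_decision = PHASE_DECISIONS,
                      interval_weeks = c(4, 8))
  )
  if (!task_type %in% names(specs))
    stop(sprintf("unknown task type '%s'; expected one of %s", task_type,
                 paste(names(specs), collapse = ", ")), call. = FALSE)
  specs[[task_type]]
}

#' Construct a treatment action
#'
#' @param jaw numeric length-3 jaw movement `(sagittal, vertical,
#'   transverse)` in mm
#' @param force_magnitude orthodontic force in grams, \[50, 300\]
#' @param force_direction 3-vector, normalized internally to unit norm
#' @param appliance one of brackets / wires / elastics
#' @param soft_tissue_technique one of VY_advancement / reduction / none
#' @param timing simultaneous or staged
#' @param phase_decision proceed / hold / modify
#' @param interval_weeks visit cadence in weeks, \[4, 8\]
#' @param validate error on out-of-bounds values (`TRUE`) or accept raw
#'   values for later clipping (`FALSE`)
#' @return a `treatment_action` list
#' @export
treatment_action <- function(jaw = c(0, 0, 0),
                             force_magnitude = 50,
                             force_direction = c(1, 0, 0),
                             appliance = "brackets",
                             soft_tissue_technique = "none",
                             timing = "staged",
                             phase_decision = "hold",
                             interval_weeks = 6,
                             validate = TRUE) {
  nrm <- sqrt(sum(force_direction^2))
  force_direction <- if (nrm < 1e-8) c(1, 0, 0) else force_direction / nrm
  a <- structure(list(
    jaw = as.numeric(jaw), force_magnitude = force_magnitude,
    force_direction = as.numeric(force_direction),
    appliance = appliance, soft_tissue_technique = soft_tissue_technique,
    timing = timing, phase_decision = phase_decision,
    interval_weeks = interval_weeks
  ), class = "treatment_action")
  if (validate) {
    v <- action_violations(a)
    if (length(v)) stop("action out of bounds: ", paste(v, collapse = "; "),
                        call. = FALSE)
  }
  a
}

action_violations <- function(a) {
  v <- character()
  jaw_b <- action_space_spec("jaw")
  lims <- rbind(jaw_b$sagittal_mm, jaw_b$vertical_mm, jaw_b$transverse_mm)
  ax <- c("sagittal", "vertical", "transverse")
  for (k in 1:3)
    if (a$jaw[k] < lims[k, 1] || a$jaw[k] > lims[k, 2])
      v <- c(v, sprintf("jaw.%s %.1f outside [%g, %g] mm", ax[k], a$jaw[k],
                        lims[k, 1], lims[k, 2]))
  # 0 denotes "no active appliance"; active forces obey the 50-300 g range
  if (a$force_magnitude != 0 &&
      (a$force_magnitude < 50 || a$force_magnitude > 300))
    v <- c(v, sprintf("force_magnitude %.0f outside [50, 300] g",
                      a$force_magnitude))
  if (abs(sqrt(sum(a$force_direction^2)) - 1) > 1e-6)
    v <- c(v, "force_direction not unit norm")
  if (!a$appliance %in% APPLIANCES) v <- c(v, "unknown appliance")
  if (!a$soft_tissue_technique %in% SOFT_TECHNIQUES) v <- c(v, "unknown technique")
  if (!a$timing %in% TIMINGS) v <- c(v, "unknown timing")
  if (!a$phase_decision %in% PHASE_DECISIONS) v <- c(v, "unknown phase_decision")
  if (a$interval_weeks < 4 || a$interval_weeks > 8)
    v <- c(v, sprintf("interval_weeks %.1f outside [4, 8]", a$interval_weeks))
  v
}

#' Clip an action into the legal bounds
#'
#' @param action a `treatment_action` (possibly out of bounds)
#' @return list with `action` (clipped) and `clips` (character vector of
#'   fields that required clipping)
#' @export
clip_action <- function(action) {
  clips <- character()
  jb <- action_space_spec("jaw")
  lims <- rbind(jb$sagittal_mm, jb$vertical_mm, jb$transverse_mm)
  jaw <- action$jaw
  for (k in 1:3) {
    cl <- clamp(jaw[k], lims[k, 1], lims[k, 2])
    if (cl != jaw[k]) clips <- c(clips, c("jaw.sagittal", "jaw.vertical",
                                          "jaw.transverse")[k])
    jaw[k] <- cl
  }
  fm <- if (action$force_magnitude == 0) 0
        else clamp(action$force_magnitude, 50, 300)
  if (fm != action$force_magnitude) clips <- c(clips, "force_magnitude")
  iv <- clamp(action$interval_weeks, 4, 8)
  if (iv != action$interval_weeks) clips <- c(clips, "interval_weeks")
  out <- action
  out$jaw <- jaw; out$force_magnitude <- fm; out$interval_weeks <- iv
  nrm <- sqrt(sum(out$force_direction^2))
  out$force_direction <- if (nrm < 1e-8) c(1, 0, 0) else out$force_direction / nrm
  list(action = out, clips = clips)
}

#' Uniformly random in-bounds action
#'
#' The random baseline policy: every continuous component uniform in its
#' bounds, every categorical component uniform over its vocabulary.
#'
#' @return a `treatment_action`
#' @export
random_action <- function() {
  dir <- stats::rnorm(3)
  treatment_action(
    jaw = c(stats::runif(1, -15, 15), stats::runif(1, -10, 10),
            stats::runif(1, -8, 8)),
    force_magnitude = stats::runif(1, 50, 300),
    force_direction = dir,
    appliance = sample(APPLIANCES, 1),
    soft_tissue_technique = sample(SOFT_TECHNIQUES, 1),
    timing = sample(TIMINGS, 1),
    phase_decision = sample(PHASE_DECISIONS, 1),
    interval_weeks = stats::runif(1, 4, 8)
  )
}

# ---- numeric encoding used by the planner --------------------------------

CONT_DIM <- 8L   # jaw(3), force magnitude(1), force direction(3), interval(1)
CAT_SIZES <- c(appliance = 3L, technique = 3L, timing = 2L, decision = 3L)

cont_bounds <- function() {
  lo <- c(-15, -10, -8, 50, -1, -1, -1, 4)
  hi <- c(15, 10, 8, 300, 1, 1, 1, 8)
  list(lo = lo, hi = hi)
}

# continuous part mapped to [-1, 1]; categoricals one-hot
encode_action <- function(a) {
  b <- cont_bounds()
  raw <- c(a$jaw, a$force_magnitude, a$force_direction, a$interval_weeks)
  cont <- 2 * (raw - b$lo) / (b$hi - b$lo) - 1
  onehot <- function(x, lv) as.numeric(lv == x)
  c(cont, onehot(a$appliance, APPLIANCES),
    onehot(a$soft_tissue_technique, SOFT_TECHNIQUES),
    onehot(a$timing, TIMINGS), onehot(a$phase_decision, PHASE_DECISIONS))
}

action_enc_dim <- function() CONT_DIM + sum(CAT_SIZES)

# inverse of encode_action for the continuous block + categorical indices
decode_action <- function(cont_unit, cat_idx) {
  b <- cont_bounds()
  raw <- (cont_unit + 1) / 2 * (b$hi - b$lo) + b$lo
  treatment_action(
    jaw = raw[1:3], force_magnitude = raw[4], force_direction = raw[5:7],
    appliance = APPLIANCES[cat_idx[1]],
    soft_tissue_technique = SOFT_TECHNIQUES[cat_idx[2]],
    timing = TIMINGS[cat_idx[3]],
    phase_decision = PHASE_DECISIONS[cat_idx[4]],
    interval_weeks = raw[8], validate = FALSE
  )
}
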