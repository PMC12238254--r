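# Craniofacial patient state: the MDP state s_t with five blocks
# [skeletal, dental, soft_tissue, functional, treatment_status].
# Conventions used throughout: fixed right-handed head-centered frame, mm
# units, sagittal = +anterior, vertical = +superior, transverse = +right.

# Number of 3D skeletal landmarks and soft-tissue thickness points in the
# state representation, and teeth tracked in the dental block.
N_LANDMARKS <- 68L
N_THICKNESS <- 64L
N_TEETH <- 28L

IDEAL_ANB <- 2.0 # degrees; center of the normal sagittal relationship

# deterministic template face: landmarks on three para-sagittal arcs
landmark_template <- function() {
  i <- seq_len(N_LANDMARKS)
  t <- 2 * pi * i / N_LANDMARKS
  cbind(sagittal  = 45 * cos(t),
        vertical  = 55 * sin(t),
        transverse = rep(c(-25, 0, 25), length.out = N_LANDMARKS))
}

tooth_template <- function() {
  i <- seq_len(N_TEETH)
  arch <- ifelse(i <= 14, 1, -1)              # upper / lower
  k <- ifelse(i <= 14, i, i - 14L)
  t <- pi * (k - 0.5) / 14
  cbind(x = 25 * cos(t), y = arch * 5, z = 30 * sin(t),
        tip = 0, torque = 0, rotation = 0)
}

# severity in [0, ~1.5]: distance from ideal sagittal relation plus
# contributions of the non-sagittal deformity labels
deformity_severity <- function(anb_deg, labels) {
  s <- abs(anb_deg - IDEAL_ANB) / 6
  if ("Asymmetry" %in% labels) s <- s + 0.25
  if ("VerticalDiscrepancy" %in% labels) s <- s + 0.2
  s
}

#' Sample a full craniofacial state for a patient record
#'
#' Populates every block of the MDP state consistently with the record: the
#' cephalometric ANB equals `record$anb_deg` exactly, the occlusal class
#' matches the record's sagittal deformity label, mandibular landmarks are
#' displaced according to the sagittal discrepancy, and dental misalignment,
#' soft-tissue harmony and functional scores degrade with deformity
#' severity. All 137 schema measurements are populated. Deterministic given
#' `seed`.
#'
#' @param record a [patient_record()]
#' @param schema a [measurement_schema()]
#' @param seed integer seed for the per-patient sampling stream
#' @return a `patient_state` object
#' @examples
#' rec <- patient_record("P1", 23, "female", "ClassIII", -2.8)
#' st <- sample_patient_state(rec, seed = 7)
#' st$skeletal$ceph[["ANB"]]  # -2.8
#' @export
sample_patient_state <- function(record, schema = measurement_schema(), seed = 1L) {
  stopifnot(inherits(record, "patient_record"))
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  anb <- record$anb_deg
  labels <- record$deformity_labels
  sev <- deformity_severity(anb, labels)
  cls <- if ("ClassIII" %in% labels) "III" else if ("ClassII" %in% labels) "II" else "I"

  sna <- clamp(stats::rnorm(1, 82, 1.5), 76, 88)
  ceph <- c(SNA = sna, SNB = sna - anb, ANB = anb)

  lm <- landmark_template()
  mand <- lm[, "vertical"] < 0                   # lower-face landmarks
  lm[mand, "sagittal"] <- lm[mand, "sagittal"] - 1.5 * (anb - IDEAL_ANB)
  if ("Asymmetry" %in% labels)
    lm[mand, "transverse"] <- lm[mand, "transverse"] + stats::rnorm(1, 3, 1)
  lm <- lm + matrix(stats::rnorm(length(lm), 0, 1.0), nrow = nrow(lm))

  teeth <- tooth_template()
  mis_sd <- 2 + 6 * min(sev, 1.2)               # degrees of crowding/tip noise
  teeth[, c("tip", "torque", "rotation")] <-
    matrix(stats::rnorm(3 * N_TEETH, 0, mis_sd), ncol = 3)
  teeth[, c("x", "z")] <- teeth[, c("x", "z")] +
    matrix(stats::rnorm(2 * N_TEETH, 0, 0.5), ncol = 2)
  arch <- c(width = clamp(stats::rnorm(1, 36, 2) -
                            2 * ("VerticalDiscrepancy" %in% labels), 25, 50),
            length = clamp(stats::rnorm(1, 30, 2), 22, 40))

  thickness <- clamp(stats::rnorm(N_THICKNESS, 12, 2), 4, 25)
  harmony <- clamp(10 - 6.5 * sev + stats::rnorm(1, 0, 0.5), 0, 10)
  soft <- list(
    thickness = thickness,
    lip_competence = as.integer(stats::runif(1) > 0.3 + 0.3 * min(sev, 1)),
    nasal_breathing = clamp(0.85 - 0.25 * sev + stats::rnorm(1, 0, 0.05), 0, 1),
    facial_harmony = harmony
  )

  functional <- list(
    occlusal_function = clamp(0.85 - 0.45 * sev + stats::rnorm(1, 0, 0.04), 0.02, 1),
    tmj_health       = clamp(0.85 - 0.20 * sev + stats::rnorm(1, 0, 0.04), 0.02, 1),
    respiratory      = clamp(0.88 - 0.25 * sev + stats::rnorm(1, 0, 0.04), 0.02, 1)
  )

  status <- list(
    phase = 1L,
    relapse_risk = clamp(0.25 + 0.15 * sev + stats::rnorm(1, 0, 0.04), 0, 1),
    bone_density = clamp(0.75 - 0.004 * (record$age_years - 22.7) +
                           stats::rnorm(1, 0, 0.04), 0.2, 1),
    tissue_adaptation = clamp(0.25 + stats::rnorm(1, 0, 0.04), 0, 1),
    elapsed_months = 0
  )

  # static residuals for the placeholder measurements; the anatomically
  # named entries are refreshed from the live blocks by state_measurements()
  resid <- stats::rnorm(length(schema$all_names))
  names(resid) <- schema$all_names

  st <- structure(list(
    skeletal = list(landmarks = lm, ceph = ceph, occlusal_class = cls),
    dental = list(teeth = teeth, arch = arch),
    soft_tissue = soft,
    functional = functional,
    treatment_status = status,
    measurement_resid = resid
  ), class = "patient_state")
  st
}

# mean absolute dental angulation error, degrees (alignment quality proxy)
dental_misalignment <- function(state) {
  mean(abs(state$dental$teeth[, c("tip", "torque", "rotation")]))
}

# profile balance in [0, 1]: improves as the sagittal relation normalizes
profile_balance <- function(state) {
  clamp(1 - abs(state$skeletal$ceph[["ANB"]] - IDEAL_ANB) / 10, 0, 1)
}

#' All 137 schema measurements for a state
#'
#' Returns the named 137-vector of craniofacial measurements. Anatomically
#' named entries (SNA, SNB, ANB, arch dimensions, harmony/profile indices,
#' mean angulations, overjet proxy, ...) are computed live from the state
#' blocks so they track treatment progress; placeholder parameters carry the
#' per-patient residuals drawn at sampling time.
#'
#' @param state a `patient_state`
#' @param schema a [measurement_schema()]
#' @return named numeric vector of length 137
#' @export
state_measurements <- function(state, schema = measurement_schema()) {
  v <- state$measurement_resid[schema$all_names]
  ceph <- state$skeletal$ceph
  anb <- ceph[["ANB"]]
  v["SNA"] <- ceph[["SNA"]]; v["SNB"] <- ceph[["SNB"]]; v["ANB"] <- anb
  v["overjet"] <- 2 + 0.8 * (anb - IDEAL_ANB)
  v["overbite"] <- 2 + 0.3 * (anb - IDEAL_ANB)
  v["upper_arch_width"] <- state$dental$arch[["width"]]
  v["upper_arch_length"] <- state$dental$arch[["length"]]
  v["lower_arch_width"] <- state$dental$arch[["width"]] - 4
  v["lower_arch_length"] <- state$dental$arch[["length"]] - 3
  v["U1_SN"] <- 104 + mean(state$dental$teeth[1:14, "tip"])
  v["L1_MP"] <- 92 + mean(state$dental$teeth[15:28, "tip"])
  v["interincisal_angle"] <- 130 - 1.5 * (anb - IDEAL_ANB)
  v["upper_lip_thickness"] <- mean(state$soft_tissue$thickness[1:16])
  v["lower_lip_thickness"] <- mean(state$soft_tissue$thickness[17:32])
  v["chin_thickness"] <- mean(state$soft_tissue$thickness[33:48])
  v["facial_convexity"] <- 12 - 1.2 * (anb - IDEAL_ANB)
  v["nasolabial_angle"] <- 100 - 2 * (anb - IDEAL_ANB)
  v["labiomental_angle"] <- 120 + v["labiomental_angle"]
  v["facial_harmony_index"] <- state$soft_tissue$facial_harmony
  v["profile_balance"] <- profile_balance(state)
  v
}

range_spec <- function() list(
  facial_harmony = c(0, 10), nasal_breathing = c(0, 1),
  occlusal_function = c(0, 1), tmj_health = c(0, 1), respiratory = c(0, 1),
  relapse_risk = c(0, 1), bone_density = c(0, 1), tissue_adaptation = c(0, 1)
)

#' Validate a patient state against its range invariants
#'
#' Checks every block: landmark/thickness/teeth dimensions, cephalometric
#' finiteness, the 0-10 facial harmony scale, the 0-1 scales of the
#' functional and healing indicators, phase in 1-4, non-negative elapsed
#' time.
#'
#' @param state a `patient_state`
#' @return a data frame of violations with columns `field`, `value`,
#'   `allowed`; zero rows iff the state is valid
#' @export
validate_state <- function(state) {
  bad <- list()
  add <- function(field, value, allowed)
    bad[[length(bad) + 1L]] <<- data.frame(
      field = field, value = as.numeric(value)[1], allowed = allowed,
      stringsAsFactors = FALSE)

  if (!is.matrix(state$skeletal$landmarks) ||
      !all(dim(state$skeletal$landmarks) == c(N_LANDMARKS, 3L)))
    add("skeletal.landmarks", NA, "68 x 3 matrix (mm)")
  else if (!all(is.finite(state$skeletal$landmarks)))
    add("skeletal.landmarks", NA, "finite mm coordinates")
  if (!all(is.finite(state$skeletal$ceph)) || length(state$skeletal$ceph) != 3L)
    add("skeletal.ceph", NA, "finite SNA/SNB/ANB degrees")
  if (!state$skeletal$occlusal_class %in% c("I", "II", "III"))
    add("skeletal.occlusal_class", NA, "one of I, II, III")
  if (!is.matrix(state$dental$teeth) ||
      !all(dim(state$dental$teeth) == c(N_TEETH, 6L)) ||
      !all(is.finite(state$dental$teeth)))
    add("dental.teeth", NA, "28 x 6 finite matrix")
  if (any(state$dental$arch <= 0) || !all(is.finite(state$dental$arch)))
    add("dental.arch", state$dental$arch[1], "positive mm dimensions")
  if (length(state$soft_tissue$thickness) != N_THICKNESS ||
      any(state$soft_tissue$thickness < 0 | state$soft_tissue$thickness > 40))
    add("soft_tissue.thickness", state$soft_tissue$thickness[1],
        "64 points in [0, 40] mm")
  if (!state$soft_tissue$lip_competence %in% c(0L, 1L))
    add("soft_tissue.lip_competence", state$soft_tissue$lip_competence, "{0, 1}")

  scalar_checks <- list(
    c("soft_tissue", "nasal_breathing", "nasal_breathing"),
    c("soft_tissue", "facial_harmony", "facial_harmony"),
    c("functional", "occlusal_function", "occlusal_function"),
    c("functional", "tmj_health", "tmj_health"),
    c("functional", "respiratory", "respiratory"),
    c("treatment_status", "relapse_risk", "relapse_risk"),
    c("treatment_status", "bone_density", "bone_density"),
    c("treatment_status", "tissue_adaptation", "tissue_adaptation")
  )
  rs <- range_spec()
  for (chk in scalar_checks) {
    val <- state[[chk[1]]][[chk[2]]]
    rng <- rs[[chk[3]]]
    if (!is_scalar_num(val) || val < rng[1] || val > rng[2])
      add(paste(chk[1], chk[2], sep = "."), val,
          sprintf("scale [%g, %g]", rng[1], rng[2]))
  }
  if (!state$treatment_status$phase %in% 1:4)
    add("treatment_status.phase", state$treatment_status$phase, "phase 1-4 scale")
  if (!is_scalar_num(state$treatment_status$elapsed_months) ||
      state$treatment_status$elapsed_months < 0)
    add("treatment_status.elapsed_months", state$treatment_status$elapsed_months,
        ">= 0 months")

  if (length(bad) == 0L)
    data.frame(field = character(), value = numeric(), allowed = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, bad)
}

#' Compact numeric feature projection of a state
#'
#' The standardized summary vector consumed by the planner's encoders:
#' cephalometrics, occlusal class, dental alignment summaries, arch
#' dimensions, soft-tissue and functional scores, treatment-status block and
#' the signed gap to the ideal ANB. All entries are scaled to roughly
#' \[-1, 1\].
#'
#' @param state a `patient_state`
#' @param horizon_months normalizer for elapsed time
#' @return named numeric vector (length [state_feature_dim()])
#' @export
state_features <- function(state, horizon_months = 40) {
  ceph <- state$skeletal$ceph
  cls <- state$skeletal$occlusal_class
  ph <- state$treatment_status$phase
  ang <- state$dental$teeth[, c("tip", "torque", "rotation")]
  c(sna = (ceph[["SNA"]] - 82) / 10,
    snb = (ceph[["SNB"]] - 80) / 10,
    anb = ceph[["ANB"]] / 10,
    anb_gap = (ceph[["ANB"]] - IDEAL_ANB) / 10,
    cls_I = as.numeric(cls == "I"), cls_II = as.numeric(cls == "II"),
    cls_III = as.numeric(cls == "III"),
    mis_tip = mean(abs(ang[, 1])) / 10, mis_torque = mean(abs(ang[, 2])) / 10,
    mis_rot = mean(abs(ang[, 3])) / 10,
    arch_w = (state$dental$arch[["width"]] - 36) / 10,
    arch_l = (state$dental$arch[["length"]] - 30) / 10,
    thick = (mean(state$soft_tissue$thickness) - 12) / 6,
    lip = state$soft_tissue$lip_competence,
    nasal = state$soft_tissue$nasal_breathing,
    harmony = state$soft_tissue$facial_harmony / 10,
    occ = state$functional$occlusal_function,
    tmj = state$functional$tmj_health,
    resp = state$functional$respiratory,
    ph1 = as.numeric(ph == 1L), ph2 = as.numeric(ph == 2L),
    ph3 = as.numeric(ph == 3L), ph4 = as.numeric(ph == 4L),
    relapse = state$treatment_status$relapse_risk,
    bone = state$treatment_status$bone_density,
    adapt = state$treatment_status$tissue_adaptation,
    elapsed = state$treatment_status$elapsed_months / horizon_months)
}

#' @rdname state_features
#' @export
state_feature_dim <- function() 27L

#' @export
print.patient_state <- function(x, ...) {
  cat(sprintf(
    "<patient_state> class %s, ANB %.1f deg, harmony %.1f/10, phase %d, %.1f mo elapsed\n",
    x$skeletal$occlusal_class, x$skeletal$ceph[["ANB"]],
    x$soft_tissue$facial_harmony, x$treatment_status$phase,
    x$treatment_status$elapsed_months))
  invisible(x)
}
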