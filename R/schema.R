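#' The 137-measurement craniofacial schema
#'
#' The feature-extraction protocol summarizes each patient by 137 craniofacial
#' measurements: 45 skeletal parameters (cephalometric angles such as SNA,
#' SNB, ANB, facial heights, and further skeletal descriptors), 52 dental
#' measurements (tooth positions, angulations, arch dimensions) and 40 soft
#' tissue metrics (profile angles and tissue thickness). Only a handful of
#' measurement names are anatomically standard; the remainder are documented
#' placeholder parameters that complete the published 45/52/40 grouping.
#'
#' @return an object of class `measurement_schema`: a list with character
#'   vectors `skeletal_names` (45), `dental_names` (52), `soft_tissue_names`
#'   (40) and `all_names` (137, unique).
#' @examples
#' sch <- measurement_schema()
#' length(sch$all_names)  # 137
#' @export
measurement_schema <- function() {
  skeletal <- c(
    "SNA", "SNB", "ANB", "FMA", "SN_MP", "gonial_angle",
    "anterior_facial_height", "posterior_facial_height", "facial_height_ratio",
    "wits_appraisal", "y_axis_angle", "palatal_plane_angle",
    paste0("skeletal_p", sprintf("%02d", seq_len(33)))
  )
  dental <- c(
    "U1_SN", "L1_MP", "interincisal_angle", "overjet", "overbite",
    "upper_arch_width", "upper_arch_length", "lower_arch_width",
    "lower_arch_length", "curve_of_spee",
    paste0("dental_p", sprintf("%02d", seq_len(42)))
  )
  soft <- c(
    "nasolabial_angle", "labiomental_angle", "facial_convexity",
    "upper_lip_thickness", "lower_lip_thickness", "chin_thickness",
    "facial_harmony_index", "profile_balance",
    paste0("soft_p", sprintf("%02d", seq_len(32)))
  )
  stopifnot(length(skeletal) == 45L, length(dental) == 52L, length(soft) == 40L)
  all_names <- c(skeletal, dental, soft)
  stopifnot(!anyDuplicated(all_names))
  structure(
    list(skeletal_names = skeletal, dental_names = dental,
         soft_tissue_names = soft, all_names = all_names),
    class = "measurement_schema"
  )
}

#' @export
print.measurement_schema <- function(x, ...) {
  cat("<measurement_schema> 137 measurements:",
      length(x$skeletal_names), "skeletal,",
      length(x$dental_names), "dental,",
      length(x$soft_tissue_names), "soft tissue\n")
  invisible(x)
}
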