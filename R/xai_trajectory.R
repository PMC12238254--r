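# Trajectory explanation: decompose an episode into treatment phases,
# identify the reward component dominating each phase, and justify each
# transition by its reward-component deltas. Reports are rendered from
# fixed templates at two audience levels.

#' Phase-decomposed explanation of a treatment trajectory
#'
#' Segments the trajectory by treatment phase; within each segment the
#' dominant objective is the argmax of the weighted summed rewards
#' `sum_t w_i r_{i,t}`. Each transition record carries the action summary
#' and the reward-component contributions justifying it.
#'
#' @param traj a trajectory from [rollout_episode()]
#' @param w a [task_weights()]
#' @return class `trajectory_explanation`: list with `segments` (data
#'   frame: phase, from_step, to_step, dominant_component, months) and
#'   `transitions` (per-step justification records)
#' @export
explain_trajectory <- function(traj, w = task_weights()) {
  if (length(traj) == 0L) stop("trajectory must be non-empty", call. = FALSE)
  wn <- as.numeric(w)
  comp_names <- c("functional", "aesthetic", "efficiency", "stability")
  phases <- vapply(traj, function(x) x$state$treatment_status$phase, integer(1))
  R <- t(vapply(traj, function(x) as.numeric(x$reward), numeric(4)))

  runs <- rle(phases)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  segments <- do.call(rbind, lapply(seq_along(runs$values), function(k) {
    span <- starts[k]:ends[k]
    wsum <- colSums(R[span, , drop = FALSE]) * wn
    data.frame(phase = runs$values[k], from_step = starts[k],
               to_step = ends[k],
               dominant_component = comp_names[which.max(wsum)],
               months = traj[[ends[k]]]$next_state$treatment_status$elapsed_months -
                 traj[[starts[k]]]$state$treatment_status$elapsed_months)
  }))

  transitions <- lapply(seq_along(traj), function(t) {
    a <- traj[[t]]$action
    list(step = t, phase = phases[t],
         action = sprintf(
           "jaw (%.1f, %.1f, %.1f) mm; force %.0f g (%s); %s; %s; every %.1f wk",
           a$jaw[1], a$jaw[2], a$jaw[3], a$force_magnitude, a$appliance,
           a$soft_tissue_technique, a$phase_decision, a$interval_weeks),
         reward_components = stats::setNames(as.numeric(R[t, ]), comp_names),
         weighted_reward = sum(wn * R[t, ]))
  })
  structure(list(segments = segments, transitions = transitions, weights = w),
            class = "trajectory_explanation")
}

#' Render an explanation as a clinical report
#'
#' Template-based rendering of any explanation object. `specialist` mode
#' includes numeric tables; `interdisciplinary` mode gives only ranked
#' qualitative statements. Feature rankings are identical across audiences.
#'
#' @param x an `attribution`, `surrogate_rules`, `counterfactual` or
#'   `trajectory_explanation`
#' @param audience `"specialist"` or `"interdisciplinary"`
#' @param top_k number of features/items listed
#' @return class `explanation_report`: list with `text` (character lines,
#'   Markdown) and `data` (structured document for machine use)
#' @export
render_report <- function(x, audience = c("specialist", "interdisciplinary"),
                          top_k = 5L) {
  if (length(audience) > 1L) audience <- audience[1L]
  if (!audience %in% c("specialist", "interdisciplinary"))
    stop("unknown audience; use 'specialist' or 'interdisciplinary'",
         call. = FALSE)
  UseMethod("render_report")
}

#' @export
render_report.attribution <- function(x, audience = "specialist", top_k = 5L) {
  ord <- order(-abs(x$contributions))
  k <- min(top_k, length(ord))
  sel <- ord[seq_len(k)]
  nm <- names(x$contributions)[sel] %||% paste0("feature_", sel)
  lines <- c("## Feature attribution", "")
  if (audience == "specialist") {
    lines <- c(lines, sprintf("Model output %.4f (baseline %.4f).",
                              x$target, x$target_baseline),
               "", "| rank | feature | contribution |", "|---|---|---|",
               sprintf("| %d | %s | %+.4f |", seq_len(k), nm,
                       x$contributions[sel]))
  } else {
    dir <- ifelse(x$contributions[sel] >= 0, "supports", "opposes")
    lines <- c(lines, sprintf("%d. %s %s the recommendation.",
                              seq_len(k), nm, dir))
  }
  structure(list(text = lines,
                 data = list(kind = "attribution", audience = audience,
                             ranking = nm,
                             contributions = unname(x$contributions[sel]))),
            class = "explanation_report")
}

#' @export
render_report.surrogate_rules <- function(x, audience = "specialist",
                                          top_k = 5L) {
  lines <- c("## Surrogate decision rules", "")
  if (x$degenerate) {
    lines <- c(lines, sprintf(
      "The policy is constant: it always recommends '%s' (fidelity %.2f).",
      x$constant, x$fidelity))
  } else if (audience == "specialist") {
    lines <- c(lines, sprintf("Held-out fidelity: %.3f (n = %d).",
                              x$fidelity, x$n_test), "",
               utils::capture.output(print(x$tree)))
  } else {
    lines <- c(lines, sprintf(
      "A simple rule set reproduces the planner's choice in %.0f%% of cases.",
      100 * x$fidelity))
  }
  structure(list(text = lines,
                 data = list(kind = "surrogate", audience = audience,
                             fidelity = x$fidelity,
                             degenerate = x$degenerate)),
            class = "explanation_report")
}

#' @export
render_report.counterfactual <- function(x, audience = "specialist",
                                         top_k = 5L) {
  lines <- c("## Counterfactual scenario", "")
  if (!x$feasible) {
    lines <- c(lines, "No biologically feasible modification reaches the requested outcome.")
  } else if (x$sparsity == 0) {
    lines <- c(lines, "The current state already satisfies the target; no modification needed.")
  } else {
    ch <- which(abs(x$deltas) > 1e-12)
    ch <- ch[order(-abs(x$deltas[ch]))]
    ch <- ch[seq_len(min(top_k, length(ch)))]
    nm <- names(x$original)[ch] %||% paste0("feature_", ch)
    if (audience == "specialist") {
      lines <- c(lines, sprintf(
        "Minimal modification: %d feature(s), weighted L1 distance %.3f, achieved output %.4f.",
        x$sparsity, x$distance, x$achieved), "",
        "| feature | from | to | delta |", "|---|---|---|---|",
        sprintf("| %s | %.3f | %.3f | %+.3f |", nm, x$original[ch],
                x$modified[ch], x$deltas[ch]))
    } else {
      dir <- ifelse(x$deltas[ch] > 0, "increase", "decrease")
      lines <- c(lines, sprintf("%d. %s %s.", seq_along(ch), dir, nm))
    }
  }
  structure(list(text = lines,
                 data = list(kind = "counterfactual", audience = audience,
                             feasible = x$feasible, sparsity = x$sparsity,
                             distance = x$distance)),
            class = "explanation_report")
}

#' @export
render_report.trajectory_explanation <- function(x, audience = "specialist",
                                                 top_k = 5L) {
  seg <- x$segments
  lines <- c("## Treatment trajectory", "")
  for (k in seq_len(nrow(seg))) {
    lines <- c(lines, sprintf(
      "Phase %d (steps %d-%d, %.1f months): dominated by the %s objective.",
      seg$phase[k], seg$from_step[k], seg$to_step[k], seg$months[k],
      seg$dominant_component[k]))
  }
  if (audience == "specialist") {
    lines <- c(lines, "", "| step | phase | action | weighted reward |",
               "|---|---|---|---|",
               vapply(x$transitions, function(tr)
                 sprintf("| %d | %d | %s | %.3f |", tr$step, tr$phase,
                         tr$action, tr$weighted_reward), character(1)))
  }
  structure(list(text = lines,
                 data = list(kind = "trajectory", audience = audience,
                             segments = seg)),
            class = "explanation_report")
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
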