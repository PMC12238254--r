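# Patient-record JSON schema, run configuration files, and the end-to-end
# pipeline (cohort -> train -> evaluate -> explain) with a reproducibility
# manifest.

PATIENT_FIELDS <- c("id", "age_years", "sex", "deformity_labels", "anb_deg",
                    "treatment_duration_months", "enrollment_index",
                    "record_seed")
PATIENT_REQUIRED <- c("id", "age_years", "sex", "deformity_labels", "anb_deg")

#' Read / write a patient record as JSON
#'
#' The documented schema: `id` (string), `age_years` (years, \[18, 35\]),
#' `sex` (`"female"`/`"male"`), `deformity_labels` (array), `anb_deg`
#' (degrees), optional `treatment_duration_months` (months),
#' `enrollment_index`, `record_seed`. Unknown fields are rejected with a
#' schema error listing them; round-trips are lossless.
#'
#' @param path JSON file path
#' @param record a [patient_record()]
#' @return `read_patient` returns the record; `write_patient` returns
#'   `path` invisibly
#' @export
read_patient <- function(path) {
  x <- jsonlite::fromJSON(path)
  unknown <- setdiff(names(x), PATIENT_FIELDS)
  if (length(unknown))
    stop("schema error: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(PATIENT_REQUIRED, names(x))
  if (length(missing))
    stop("schema error: missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  patient_record(x$id, x$age_years, x$sex, x$deformity_labels, x$anb_deg,
                 x$treatment_duration_months %||% NA_real_,
                 x$enrollment_index %||% NA_integer_,
                 x$record_seed)
}

#' @rdname read_patient
#' @export
write_patient <- function(record, path) {
  stopifnot(inherits(record, "patient_record"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the sub-configurations of a full pipeline run. Serializes to and
#' from YAML losslessly via [write_run_config()] / [read_run_config()].
#'
#' @param cohort_n cohort size
#' @param seed global seed; stage seeds are derived from it
#' @param train_steps SAC training steps
#' @param eval_episodes evaluation episodes per policy
#' @param weights a [task_weights()]
#' @param out_dir output directory
#' @param log_level `"info"` or `"debug"`
#' @return a `run_config` list
#' @export
run_config <- function(cohort_n = 50L, seed = 1L, train_steps = 2000L,
                       eval_episodes = 20L, weights = task_weights(),
                       out_dir = tempfile("orthoplanr_run_"),
                       log_level = "info") {
  if (cohort_n < 1L) stop_config("cohort_n", "must be >= 1")
  if (train_steps < 1L) stop_config("train_steps", "must be >= 1")
  structure(list(cohort_n = as.integer(cohort_n), seed = as.integer(seed),
                 train_steps = as.integer(train_steps),
                 eval_episodes = as.integer(eval_episodes),
                 weights = as.numeric(weights), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_config("path", sprintf("config file not found: %s", path))
  x <- yaml::read_yaml(path)
  w <- x$weights
  run_config(x$cohort_n, x$seed, x$train_steps, x$eval_episodes,
             task_weights(w[1], w[2], w[3], w[4]), x$out_dir, x$log_level)
}

log_line <- function(level, ...) {
  cat(sprintf("ts=%s level=%s %s\n",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level,
              paste(..., collapse = " ")))
}

#' Run the full planning pipeline
#'
#' Executes the stages in order — simulate-cohort, train, evaluate
#' (trained vs random policy), explain (attribution, surrogate,
#' counterfactual, trajectory for the first test patient) — writing each
#' stage's artifacts plus a manifest (package version, seeds, config, file
#' MD5 hashes) into `config$out_dir`. Deterministic stages are idempotent
#' given an identical config and seed. A stage failure aborts with an error
#' naming the stage; prior outputs are retained next to a `FAILED_<stage>`
#' marker.
#'
#' @param config a [run_config()]
#' @return the artifact directory path, invisibly
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    log_line("info", sprintf("stage=%s status=start", name))
    tryCatch(expr, error = function(e) {
      writeLines(conditionMessage(e), out(paste0("FAILED_", name)))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  w <- task_weights(config$weights[1], config$weights[2],
                    config$weights[3], config$weights[4])

  cohort <- stage("simulate-cohort", {
    cc <- cohort_config(n = config$cohort_n, seed = config$seed)
    ch <- sample_cohort(cc)
    write_cohort(ch, out("cohort.jsonl"))
    write_feature_table(ch, out("cohort_features.csv"))
    ch
  })

  env_cfg <- env_config(seed = derive_seed(config$seed, 2L))
  trained <- stage("train", {
    env <- treatment_env(cohort, env_cfg)
    tc <- train_config(steps = config$train_steps, weights = w,
                       warmup_steps = min(500L, config$train_steps %/% 4L),
                       batch_size = 128L, eval_every =
                         max(100L, config$train_steps %/% 10L),
                       seed = derive_seed(config$seed, 3L))
    res <- train_planner(treatment_rl_env(env), tc)
    utils::write.csv(res$log, out("training_log.csv"), row.names = FALSE)
    res
  })

  comparison <- stage("evaluate", {
    env <- treatment_env(cohort, env_cfg)
    cmp <- compare_policies(
      env, list(trained = planner_policy(trained$agent), random = random_policy()),
      n_episodes = config$eval_episodes, seed = derive_seed(config$seed, 4L),
      w = w)
    utils::write.csv(cmp$summary, out("evaluation_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cmp$pairwise, out("evaluation_pairwise.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    cmp
  })

  stage("explain", {
    env <- treatment_env(cohort, env_cfg)
    rec <- cohort[[1]]
    st <- env_reset(rec, env_cfg)
    sch <- measurement_schema()
    x <- state_measurements(st, sch)
    base <- x * 0
    qmodel <- function(M) apply(M, 1, function(row) sum(row * seq_along(row)) / 1e4)
    attr_obj <- feature_attribution(qmodel, x, base, n_samples = 16L,
                                    seed = derive_seed(config$seed, 5L))
    pol <- planner_policy(trained$agent)
    # several sampled states per patient so the surrogate has a real sample
    feats <- do.call(rbind, lapply(cohort, function(r) {
      t(vapply(1:5, function(k) {
        st_k <- sample_patient_state(r, sch, seed = derive_seed(r$record_seed, k))
        state_features(st_k, env_cfg$horizon_months)
      }, numeric(state_feature_dim())))
    }))
    pfun <- function(df) apply(df, 1, function(fr) {
      a <- policy_sample_features(trained$agent, as.numeric(fr))
      a$phase_decision
    })
    sur <- fit_surrogate(pfun, as.data.frame(feats),
                         seed = derive_seed(config$seed, 6L))
    traj <- rollout_episode(env, pol, record_index = 1L)
    texp <- explain_trajectory(traj, w)
    rep1 <- render_report(attr_obj, "specialist")
    rep2 <- render_report(texp, "interdisciplinary")
    writeLines(c(rep1$text, "", rep2$text), out("explanations.md"))
    jsonlite::write_json(list(attribution = rep1$data, surrogate = list(
      fidelity = sur$fidelity, degenerate = sur$degenerate),
      trajectory = rep2$data), out("explanations.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    invisible(NULL)
  })

  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package = "orthoplanr",
    version = as.character(utils::packageVersion("orthoplanr")),
    seed = config$seed, config = unclass(config),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    hashes = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_line("info", "stage=done", sprintf("out_dir=%s", config$out_dir))
  invisible(config$out_dir)
}

# policy head decision for a raw feature vector (no patient_state needed)
policy_sample_features <- function(agent, features, deterministic = TRUE) {
  sm <- policy_sample_raw(agent$policy, matrix(features, nrow = 1),
                          agent$space, deterministic = deterministic)
  decode_action(as.numeric(sm$cont), as.integer(sm$cat_idx))
}

#' Produce a treatment plan report for one patient
#'
#' Rolls the trained planner out deterministically on the patient and
#' assembles the recommended action sequence, predicted outcome trajectory
#' and final TPQS.
#'
#' @param agent trained agent
#' @param record a [patient_record()]
#' @param config an [env_config()]
#' @param w a [task_weights()]
#' @return a `plan_report` list (also serializable with
#'   [jsonlite::write_json()])
#' @export
plan_report <- function(agent, record, config = env_config(),
                        w = task_weights()) {
  env <- treatment_env(list(record), config)
  traj <- rollout_episode(env, planner_policy(agent,
                                              horizon_months = config$horizon_months),
                          record_index = 1L)
  fin <- traj[[length(traj)]]$next_state
  steps <- lapply(seq_along(traj), function(t) {
    a <- traj[[t]]$action
    list(step = t,
         month = traj[[t]]$state$treatment_status$elapsed_months,
         jaw_mm = a$jaw, force_g = a$force_magnitude,
         appliance = a$appliance, technique = a$soft_tissue_technique,
         phase_decision = a$phase_decision,
         interval_weeks = a$interval_weeks,
         predicted_anb_deg = traj[[t]]$next_state$skeletal$ceph[["ANB"]],
         predicted_harmony_0_10 = traj[[t]]$next_state$soft_tissue$facial_harmony)
  })
  structure(list(
    patient_id = record$id,
    plan = steps,
    months_total = fin$treatment_status$elapsed_months,
    tpqs = compute_tpqs(tpqs_input_from_state(fin, config$horizon_months), w),
    weights = as.numeric(w)
  ), class = "plan_report")
}
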