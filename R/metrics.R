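# Evaluation formulas: outcome-forecast accuracy, the normalized
# efficiency index, the clinician confidence score, chronological data
# partitioning, and the paired policy-comparison harness.

#' Outcome-forecast accuracy at a time point
#'
#' `Accuracy(t) = 1 - (1/m) * sum_j |yhat_j(t) - y_j(t)| / y_j(t)` over the
#' `m` outcome measures. Equals 1 iff every prediction is exact and can be
#' negative for large relative errors. A zero actual value makes the
#' formula undefined and raises an error naming the outcome — no silent
#' epsilon smoothing.
#'
#' @param predicted,actual numeric vectors of predicted and actual outcome
#'   values at the evaluation time (optionally named)
#' @return the accuracy value (scale-invariant in joint rescalings)
#' @examples
#' accuracy_at(c(12, 20), c(10, 20))  # 0.9
#' @export
accuracy_at <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual), length(actual) >= 1L)
  zero <- which(actual == 0)
  if (length(zero)) {
    nm <- names(actual)[zero[1]] %||% as.character(zero[1])
    stop(sprintf(
      "actual value for outcome '%s' is zero; Accuracy(t) is undefined there",
      nm), call. = FALSE)
  }
  1 - mean(abs(predicted - actual) / abs(actual))
}

#' Normalized treatment-efficiency index
#'
#' `Efficiency = Q_outcome / (dT_treatment * C_resources)`. Resource cost is
#' dimensionless with default 1.
#'
#' @param q_outcome outcome quality
#' @param dt_treatment treatment duration (months), > 0
#' @param c_resources resource utilization, > 0
#' @return the index (halving the duration doubles it)
#' @examples
#' efficiency_index(80, 26.3)  # 3.0418...
#' @export
efficiency_index <- function(q_outcome, dt_treatment, c_resources = 1.0) {
  if (!is_scalar_num(dt_treatment) || dt_treatment <= 0)
    stop("treatment duration must be > 0", call. = FALSE)
  if (!is_scalar_num(c_resources) || c_resources <= 0)
    stop("resource cost must be > 0", call. = FALSE)
  q_outcome / (dt_treatment * c_resources)
}

#' Clinician confidence score
#'
#' `Confidence = alpha * Explainability + beta * EvidenceStrength +
#' gamma * ConsensusAlignment`, with sub-scores in \[0, 1\] and
#' non-negative weights summing to one (equal weights by default).
#'
#' @param explainability,evidence_strength,consensus_alignment sub-scores
#'   in \[0, 1\]
#' @param alpha,beta,gamma non-negative weights summing to 1
#' @return the weighted sum, in \[0, 1\]
#' @examples
#' confidence_score(0.8, 0.6, 0.9)  # 0.7667
#' @export
confidence_score <- function(explainability, evidence_strength,
                             consensus_alignment,
                             alpha = 1 / 3, beta = 1 / 3, gamma = 1 / 3) {
  s <- c(explainability, evidence_strength, consensus_alignment)
  if (any(s < 0 | s > 1)) stop("sub-scores must lie in [0, 1]", call. = FALSE)
  w <- c(alpha, beta, gamma)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  sum(w * s)
}

#' Chronological train/validation/test partition
#'
#' Sorts records ascending by the ordering key and assigns the earliest to
#' training, then validation, then testing, so evaluation predictions use
#' only historically available data. Split sizes are round-to-nearest of
#' `fraction * N` for train and validation, with the test split absorbing
#' the remainder.
#'
#' @param records list of records (e.g. [patient_record()]s) carrying the
#'   ordering key
#' @param fractions length-3 non-negative fractions summing to 1
#'   (train, validation, test)
#' @param key field name used for chronological ordering
#' @return list with `train`, `validation`, `test` record lists
#' @examples
#' # 347 cases at 70/15/15 -> sizes 243, 52, 52
#' @export
partition_chronological <- function(records,
                                    fractions = c(0.70, 0.15, 0.15),
                                    key = "enrollment_index") {
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0))
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  n <- length(records)
  if (n == 0L) return(list(train = list(), validation = list(), test = list()))
  keys <- vapply(records, function(r) as.numeric(r[[key]]), numeric(1))
  if (any(is.na(keys))) stop(sprintf("records must carry the ordering key '%s'",
                                     key), call. = FALSE)
  ord <- order(keys)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  list(train = records[ord[seq_len(n_train)]],
       validation = records[ord[n_train + seq_len(n_val)]],
       test = records[ord[n_train + n_val + seq_len(n_test)]])
}

#' Paired permutation test
#'
#' Sign-flip permutation test on paired differences. With `n_perm` random
#' sign assignments, the p-value is `(1 + #{|T*| >= |T|}) / (n_perm + 1)`
#' (two-sided) or the analogous one-sided count.
#'
#' @param x,y paired numeric samples
#' @param n_perm number of permutations
#' @param alternative `"two.sided"`, `"greater"` (mean of `x - y` > 0) or
#'   `"less"`
#' @param seed permutation seed
#' @return list with `statistic` (mean difference) and `p_value`
#' @export
paired_permutation_test <- function(x, y, n_perm = 999L,
                                    alternative = "two.sided", seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  d <- x - y
  tobs <- mean(d)
  n <- length(d)
  tstar <- vapply(seq_len(n_perm), function(i) {
    mean(d * sample(c(-1, 1), n, replace = TRUE))
  }, numeric(1))
  p <- switch(alternative,
    two.sided = (1 + sum(abs(tstar) >= abs(tobs))) / (n_perm + 1),
    greater = (1 + sum(tstar >= tobs)) / (n_perm + 1),
    less = (1 + sum(tstar <= tobs)) / (n_perm + 1),
    stop("unknown alternative", call. = FALSE))
  list(statistic = tobs, p_value = p)
}

#' Compare policies on the treatment environment
#'
#' Evaluates each policy on the same seeded episode set (paired design) and
#' reports per-policy means and standard deviations of the scalarized
#' return, per-task returns and episode TPQS, plus pairwise relative TPQS
#' improvements and paired permutation p-values (Bonferroni-corrected
#' across the two compared metrics: scalarized return and TPQS). A paired
#' t-test variant is available via `test = "t"`.
#'
#' @param env a [treatment_env()]
#' @param policies named list of policy functions `state ->
#'   treatment_action` (at least two)
#' @param n_episodes evaluation episodes per policy
#' @param seed evaluation seed (shared across policies for pairing)
#' @param w a [task_weights()]
#' @param gamma discount factor
#' @param test `"permutation"` (default) or `"t"`
#' @param n_perm permutations for the default test
#' @return list with `summary` (one row per policy) and `pairwise` (rows:
#'   policy pair, metric, improvement, raw and Bonferroni-corrected p)
#' @export
compare_policies <- function(env, policies, n_episodes = 50L, seed = 1L,
                             w = task_weights(), gamma = 0.99,
                             test = "permutation", n_perm = 999L) {
  if (length(policies) < 2L) stop("need at least two policies", call. = FALSE)
  if (is.null(names(policies)))
    names(policies) <- paste0("policy", seq_along(policies))
  evals <- lapply(policies, function(p)
    evaluate_policy(env, p, n_episodes, seed = seed, w = w, gamma = gamma))

  summary <- do.call(rbind, lapply(names(evals), function(nm) {
    e <- evals[[nm]]
    data.frame(policy = nm,
               return_mean = mean(e$return_scalar),
               return_sd = stats::sd(e$return_scalar),
               functional = mean(e$return_functional),
               aesthetic = mean(e$return_aesthetic),
               efficiency = mean(e$return_efficiency),
               stability = mean(e$return_stability),
               tpqs_mean = mean(e$tpqs), tpqs_sd = stats::sd(e$tpqs))
  }))

  nms <- names(evals)
  pairs <- utils::combn(nms, 2, simplify = FALSE)
  n_metrics <- 2L  # Bonferroni across: scalarized return, TPQS
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    a <- evals[[pr[1]]]; b <- evals[[pr[2]]]
    rows <- lapply(c("return_scalar", "tpqs"), function(metric) {
      xa <- a[[metric]]; xb <- b[[metric]]
      p <- if (test == "t") stats::t.test(xa, xb, paired = TRUE)$p.value
           else paired_permutation_test(xa, xb, n_perm = n_perm,
                                        seed = seed)$p_value
      impr <- if (metric == "tpqs")
        relative_improvement(mean(xa), mean(xb))
      else round_half_away(100 * (mean(xa) - mean(xb)) /
                             max(abs(mean(xb)), 1e-12), 1)
      data.frame(a = pr[1], b = pr[2], metric = metric,
                 improvement_pct = impr, p_raw = p,
                 p_bonferroni = min(1, p * n_metrics))
    })
    do.call(rbind, rows)
  }))
  list(summary = summary, pairwise = pairwise, episodes = evals)
}
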