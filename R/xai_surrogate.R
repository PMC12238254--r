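# Decision-tree policy surrogates: distill a discrete action component of
# the planner into an interpretable depth-bounded tree and report its
# fidelity on held-out states.

#' Fit a decision-tree surrogate of a policy
#'
#' Trains a CART tree (via rpart) mapping state features to the policy's
#' discrete action choice, and reports fidelity — the agreement fraction
#' with the policy — on a held-out disjoint sample, never on the training
#' states.
#'
#' @param policy_fn function mapping a feature data frame (one row per
#'   state) to a character/factor vector of discrete decisions
#' @param states data frame or matrix of state features (rows = states);
#'   at least 20 rows
#' @param max_depth depth bound of the tree
#' @param holdout_frac fraction of states held out for the fidelity
#'   estimate
#' @param seed split/tree seed
#' @return class `surrogate_rules`: list with `tree` (an rpart object or
#'   `NULL` for a constant policy), `fidelity`, `constant` (majority label
#'   if degenerate), `degenerate` flag, `n_train`, `n_test`
#' @export
fit_surrogate <- function(policy_fn, states, max_depth = 3L,
                          holdout_frac = 0.3, seed = 1L) {
  states <- as.data.frame(states)
  n <- nrow(states)
  if (n < 20L) stop("need at least 20 states to fit a surrogate", call. = FALSE)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  y <- as.character(policy_fn(states))
  test_idx <- sample.int(n, max(1L, round(holdout_frac * n)))
  tr <- setdiff(seq_len(n), test_idx)

  if (length(unique(y[tr])) < 2L) {
    # constant policy: trivial one-leaf surrogate, flagged
    const <- y[tr][1]
    fid <- mean(y[test_idx] == const)
    return(structure(list(tree = NULL, fidelity = fid, constant = const,
                          degenerate = TRUE, max_depth = max_depth,
                          n_train = length(tr), n_test = length(test_idx)),
                     class = "surrogate_rules"))
  }
  df <- cbind(.decision = factor(y), states)
  fit <- rpart::rpart(.decision ~ ., data = df[tr, ], method = "class",
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = 0, minsplit = 10,
                        xval = 0))
  pred <- as.character(stats::predict(fit, newdata = df[test_idx, ], type = "class"))
  fid <- mean(pred == y[test_idx])
  structure(list(tree = fit, fidelity = fid, constant = NULL,
                 degenerate = FALSE, max_depth = max_depth,
                 n_train = length(tr), n_test = length(test_idx)),
            class = "surrogate_rules")
}

#' Predict with a surrogate
#' @param rules a `surrogate_rules`
#' @param states feature data frame
#' @return character vector of decisions
#' @export
surrogate_predict <- function(rules, states) {
  states <- as.data.frame(states)
  if (rules$degenerate) rep(rules$constant, nrow(states))
  else as.character(stats::predict(rules$tree, newdata = states, type = "class"))
}

#' @export
print.surrogate_rules <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("<surrogate_rules> constant policy '%s', fidelity %.3f\n",
                x$constant, x$fidelity))
  else {
    cat(sprintf("<surrogate_rules> depth <= %d, held-out fidelity %.3f\n",
                x$max_depth, x$fidelity))
    print(x$tree)
  }
  invisible(x)
}
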