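# Constrained counterfactual explanations: the minimal biologically
# feasible modification of a state that changes the model's output in a
# requested direction, found by projected coordinate descent with
# multi-start over per-feature candidate grids.

#' Counterfactual search
#'
#' Minimizes `sum_j u_j |x'_j - x_j| + lambda_sparsity * #\{j : x'_j != x_j\}`
#' subject to the target predicate on `model(x')` and box bounds
#' (the clinically valid ranges), over the mutable features only.
#' Coordinate descent evaluates each mutable feature over a candidate grid
#' (the discretized bound interval plus the original value) from several
#' starts: the original state, the per-coordinate best single-feature
#' modifications, and random feasible points.
#'
#' @param model function mapping a numeric matrix (rows = inputs) to a
#'   numeric vector
#' @param state numeric feature vector, must lie within `bounds`
#' @param target list `list(direction, value)` with direction `">="` or
#'   `"<="`: the predicate `model(x') >= value` (or `<=`)
#' @param bounds list with numeric vectors `lo` and `hi` of the feature
#'   bounds
#' @param lambda_sparsity penalty per modified feature
#' @param weights per-feature distance weights `u_j` (default 1)
#' @param mutable logical mask of searchable features (immutable features —
#'   e.g. demographic ones — are never modified)
#' @param grid_points candidate grid resolution per feature
#' @param n_starts number of random multi-starts
#' @param max_sweeps coordinate-descent sweep cap
#' @param seed search seed
#' @return class `counterfactual`: list with `original`, `modified`,
#'   `deltas`, `achieved` (model output at the solution), `sparsity`,
#'   `distance` (weighted L1), `objective`, `feasible` flag
#' @export
counterfactual_search <- function(model, state, target, bounds,
                                  lambda_sparsity = 0,
                                  weights = rep(1, length(state)),
                                  mutable = rep(TRUE, length(state)),
                                  grid_points = 21L, n_starts = 8L,
                                  max_sweeps = 20L, seed = 1L) {
  d <- length(state)
  lo <- bounds$lo; hi <- bounds$hi
  stopifnot(length(lo) == d, length(hi) == d, length(weights) == d,
            length(mutable) == d)
  if (any(state < lo - 1e-9 | state > hi + 1e-9))
    stop("state must lie within the clinical bounds", call. = FALSE)
  if (!target$direction %in% c(">=", "<="))
    stop("target$direction must be '>=' or '<='", call. = FALSE)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  sat <- function(y) if (target$direction == ">=") y >= target$value
                     else y <= target$value
  cost <- function(x) sum(weights * abs(x - state)) +
    lambda_sparsity * sum(abs(x - state) > 1e-12)

  grids <- lapply(seq_len(d), function(j) {
    if (!mutable[j]) return(state[j])
    unique(c(seq(lo[j], hi[j], length.out = grid_points), state[j]))
  })

  f0 <- as.numeric(model(matrix(state, nrow = 1)))
  if (sat(f0)) {
    return(structure(list(original = state, modified = state,
                          deltas = state * 0, achieved = f0, sparsity = 0L,
                          distance = 0, objective = 0, feasible = TRUE),
                     class = "counterfactual"))
  }

  mut_idx <- which(mutable)
  # single-coordinate scan: cheapest feasible one-feature edits seed the
  # multi-start set
  starts <- list(state)
  single_best <- NULL; single_obj <- Inf
  for (j in mut_idx) {
    G <- grids[[j]]
    M <- matrix(state, length(G), d, byrow = TRUE)
    M[, j] <- G
    fv <- as.numeric(model(M))
    ok <- sat(fv)
    if (any(ok)) {
      costs <- weights[j] * abs(G - state[j]) +
        lambda_sparsity * (abs(G - state[j]) > 1e-12)
      costs[!ok] <- Inf
      b <- which.min(costs)
      if (costs[b] < single_obj) {
        single_obj <- costs[b]
        single_best <- M[b, ]
      }
      starts[[length(starts) + 1L]] <- M[b, ]
    }
  }
  for (r in seq_len(n_starts)) {
    x <- state
    x[mut_idx] <- vapply(mut_idx, function(j) sample(grids[[j]], 1L),
                         numeric(1))
    starts[[length(starts) + 1L]] <- x
  }

  # one coordinate-descent pass followed by pairwise joint sweeps; the
  # pairwise stage escapes the axis-aligned local optima that interaction
  # terms (e.g. x1 * x2 thresholds) create for plain coordinate descent
  descend <- function(x) {
    for (sweep in seq_len(max_sweeps)) {
      changed <- FALSE
      cur_obj <- if (sat(as.numeric(model(matrix(x, nrow = 1))))) cost(x)
                 else Inf
      for (j in mut_idx) {
        G <- grids[[j]]
        M <- matrix(x, length(G), d, byrow = TRUE)
        M[, j] <- G
        ok <- sat(as.numeric(model(M)))
        obj <- vapply(seq_along(G), function(g)
          if (ok[g]) cost(M[g, ]) else Inf, numeric(1))
        b <- which.min(obj)
        if (is.finite(obj[b]) && obj[b] < cur_obj - 1e-12 &&
            abs(G[b] - x[j]) > 1e-12) {
          x[j] <- G[b]; cur_obj <- obj[b]; changed <- TRUE
        }
      }
      if (length(mut_idx) >= 2L && length(mut_idx) <= 8L) {
        prs <- utils::combn(mut_idx, 2L, simplify = FALSE)
        for (pr in prs) {
          G1 <- grids[[pr[1]]]; G2 <- grids[[pr[2]]]
          gg <- expand.grid(a = G1, b = G2)
          M <- matrix(x, nrow(gg), d, byrow = TRUE)
          M[, pr[1]] <- gg$a; M[, pr[2]] <- gg$b
          ok <- sat(as.numeric(model(M)))
          if (!any(ok)) next
          objs <- rep(Inf, nrow(gg))
          objs[ok] <- apply(M[ok, , drop = FALSE], 1, cost)
          b <- which.min(objs)
          if (is.finite(objs[b]) && objs[b] < cur_obj - 1e-12) {
            x[pr[1]] <- gg$a[b]; x[pr[2]] <- gg$b[b]
            cur_obj <- objs[b]; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    x
  }

  best_x <- NULL; best_obj <- Inf
  for (x0 in starts) {
    x <- descend(x0)
    fx <- as.numeric(model(matrix(x, nrow = 1)))
    if (sat(fx) && cost(x) < best_obj) { best_obj <- cost(x); best_x <- x }
  }
  if (!is.null(single_best) && single_obj < best_obj) {
    best_obj <- single_obj; best_x <- single_best
  }

  if (is.null(best_x)) {
    return(structure(list(original = state, modified = NULL,
                          deltas = NULL, achieved = NA_real_,
                          sparsity = NA_integer_, distance = NA_real_,
                          objective = NA_real_, feasible = FALSE),
                     class = "counterfactual"))
  }
  deltas <- best_x - state
  structure(list(original = state, modified = best_x, deltas = deltas,
                 achieved = as.numeric(model(matrix(best_x, nrow = 1))),
                 sparsity = sum(abs(deltas) > 1e-12),
                 distance = sum(weights * abs(deltas)),
                 objective = best_obj, feasible = TRUE),
            class = "counterfactual")
}

#' @export
print.counterfactual <- function(x, ...) {
  if (!x$feasible) cat("<counterfactual> no feasible modification found\n")
  else if (x$sparsity == 0)
    cat("<counterfactual> state already satisfies the target; no modification needed\n")
  else cat(sprintf(
    "<counterfactual> %d feature(s) modified, weighted L1 distance %.3f, output %.4f\n",
    x$sparsity, x$distance, x$achieved))
  invisible(x)
}
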