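# Minimal dense-network machinery with manual backpropagation and Adam.
# Parameters are nested lists whose leaves are numeric matrices; gradients
# mirror the structure. Serial CPU execution with R's RNG keeps training
# bit-reproducible under a fixed seed.

dense_init <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  list(W = matrix(stats::runif(nin * nout, -s, s), nin, nout),
       b = matrix(0, 1, nout))
}

# bias is recycled column-major: rep(b, each = n) lays out b[j] down column j
dense_fwd <- function(X, layer) {
  out <- X %*% layer$W
  out + rep(as.numeric(layer$b), each = nrow(out))
}

relu <- function(x) x * (x > 0)

# dY: gradient at layer output; returns grads and gradient at input
dense_bwd <- function(X, layer, dY) {
  list(grad = list(W = crossprod(X, dY), b = matrix(colSums(dY), 1)),
       dX = tcrossprod(dY, layer$W))
}

# ---- parameter-tree utilities -------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

adam_new <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  # single fused traversal of (params, grads, m, v)
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      pp <- p; mm <- m; vv <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        pp[[i]] <- r[[1]]; mm[[i]] <- r[[2]]; vv[[i]] <- r[[3]]
      }
      list(pp, mm, vv)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      list(p - lr * (m2 / c1) / (sqrt(v2 / c2) + eps), m2, v2)
    }
  }
  r <- walk(params, grads, opt$m, opt$v)
  opt$m <- r[[2]]; opt$v <- r[[3]]
  list(params = r[[1]], opt = opt)
}

soft_update <- function(target, online, tau) {
  tree_map2(function(a, b) (1 - tau) * a + tau * b, target, online)
}

# ---- multi-layer trunk ---------------------------------------------------

trunk_init <- function(nin, sizes) {
  layers <- list()
  for (k in seq_along(sizes)) {
    layers[[k]] <- dense_init(nin, sizes[k])
    nin <- sizes[k]
  }
  layers
}

trunk_forward <- function(X, trunk) {
  acts <- vector("list", length(trunk) + 1L)
  acts[[1L]] <- X
  for (k in seq_along(trunk)) acts[[k + 1L]] <- relu(dense_fwd(acts[[k]], trunk[[k]]))
  list(out = acts[[length(acts)]], acts = acts)
}

trunk_backward <- function(trunk, acts, dout) {
  grads <- vector("list", length(trunk))
  for (k in rev(seq_along(trunk))) {
    dout <- dout * (acts[[k + 1L]] > 0)
    bw <- dense_bwd(acts[[k]], trunk[[k]], dout)
    grads[[k]] <- bw$grad
    dout <- bw$dX
  }
  list(grads = grads, dX = dout)
}
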