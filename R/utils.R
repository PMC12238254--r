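#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Reporting convention for percentage figures: one decimal, halves rounded
#' away from zero (so 19.95 -> 20.0, -19.95 -> -20.0), unlike base
#' [round()]'s round-half-even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a reproducible 31-bit substream seed from a base seed and an index.
# A multiplicative mix keeps distinct (seed, index) pairs from colliding for
# the cohort sizes used here; all values stay below 2^31.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  v <- (s * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(v)
}

stop_config <- function(field, msg) {
  stop(sprintf("configuration error in `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

softmax <- function(x) {
  if (is.matrix(x)) {
    m <- x[, 1L]
    for (j in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, j])
    e <- exp(x - m)
    e / rowSums(e)
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}
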