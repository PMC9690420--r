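## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## Every stochastic operation in the package funnels through this so that
## results are reproducible from recorded seeds alone.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be coercible to integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Derive a child seed from a base seed and a stream index, kept inside the
## 32-bit integer range R requires.
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1000003 + stream * 7919) %% 2147483647L)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Probabilities are clipped away from {0,1} before any logarithm.
PROB_EPS <- 1e-7

clipProb <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

softmaxVec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

oneHot <- function(y, nClasses) {
  m <- matrix(0, length(y), nClasses)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

## Shannon entropy (natural log) of a probability vector.
shannonEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

stopifnotScalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    stop(name, " must be a finite numeric scalar")
  invisible(x)
}
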