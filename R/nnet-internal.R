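## Minimal dense-network machinery: forward/backward passes with
## hand-derived gradients and Adam updates. All four networks of the
## bundle (encoder, generator, discriminator, classifier) are stacks of
## fully connected layers operating on flattened, downsampled image
## vectors; batches are row-major matrices (samples x features).

actForward <- function(a, act) {
  switch(act,
         relu = pmax(a, 0),
         lrelu = pmax(a, 0) + 0.1 * pmin(a, 0),
         linear = a,
         sigmoid = 1 / (1 + exp(-a)),
         stop("unknown activation ", act))
}

## derivative wrt pre-activation, given pre (a) and post (z)
actBackward <- function(dZ, a, z, act) {
  switch(act,
         relu = dZ * (a > 0),
         lrelu = dZ * ifelse(a > 0, 1, 0.1),
         linear = dZ,
         sigmoid = dZ * z * (1 - z),
         stop("unknown activation ", act))
}

## He-style initialization of a dense stack.
## sizes: c(in, h1, ..., out); acts: one per layer.
mlpInit <- function(sizes, acts, seed) {
  stopifnot(length(acts) == length(sizes) - 1L)
  withSeed(seed, {
    layers <- vector("list", length(acts))
    for (l in seq_along(acts)) {
      fanIn <- sizes[l]
      sd <- sqrt(2 / fanIn)
      layers[[l]] <- list(
        W = matrix(stats::rnorm(fanIn * sizes[l + 1L], 0, sd), fanIn, sizes[l + 1L]),
        b = numeric(sizes[l + 1L]),
        act = acts[l])
    }
    list(layers = layers, adam = NULL, t = 0L)
  })
}

## Forward pass. dropMask: optional list(layer = index, mask = 0/1 matrix,
## rate = numeric); inverted-dropout scaling is applied so inference-time
## passes without a mask need no rescaling.
mlpForward <- function(net, X, dropMask = NULL) {
  caches <- vector("list", length(net$layers))
  H <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    A <- H %*% ly$W
    A <- sweep(A, 2, ly$b, "+")
    Z <- actForward(A, ly$act)
    mk <- NULL
    if (!is.null(dropMask) && dropMask$layer == l && dropMask$rate > 0) {
      mk <- dropMask$mask
      Z <- Z * mk / (1 - dropMask$rate)
    }
    caches[[l]] <- list(input = H, pre = A, post = Z, mask = mk,
                        rate = if (is.null(mk)) 0 else dropMask$rate)
    H <- Z
  }
  list(out = H, caches = caches)
}

## Backward pass from the post-activation gradient of layer `fromLayer`
## (default: the output layer) down to the input. Returns per-layer
## parameter gradients (NULL above fromLayer) and the input gradient.
mlpBackward <- function(net, caches, dOut, fromLayer = length(net$layers)) {
  grads <- vector("list", length(net$layers))
  dZ <- dOut
  for (l in seq(fromLayer, 1L)) {
    cc <- caches[[l]]
    ly <- net$layers[[l]]
    if (!is.null(cc$mask)) dZ <- dZ * cc$mask / (1 - cc$rate)
    dA <- actBackward(dZ, cc$pre, cc$post, ly$act)
    grads[[l]] <- list(dW = crossprod(cc$input, dA), db = colSums(dA))
    dZ <- tcrossprod(dA, ly$W)
  }
  list(grads = grads, dInput = dZ)
}

## For output layers whose loss gradient is naturally expressed wrt the
## pre-activation (sigmoid BCE, softmax CE) we pass dPre directly.
mlpBackwardPre <- function(net, caches, dPre) {
  L <- length(net$layers)
  grads <- vector("list", L)
  cc <- caches[[L]]
  grads[[L]] <- list(dW = crossprod(cc$input, dPre), db = colSums(dPre))
  dZ <- tcrossprod(dPre, net$layers[[L]]$W)
  if (L == 1L) return(list(grads = grads, dInput = dZ))
  low <- mlpBackward(net, caches, dZ, fromLayer = L - 1L)
  grads[seq_len(L - 1L)] <- low$grads[seq_len(L - 1L)]
  list(grads = grads, dInput = low$dInput)
}

sumGrads <- function(g1, g2) {
  if (is.null(g1)) return(g2)
  if (is.null(g2)) return(g1)
  for (l in seq_along(g1)) {
    if (is.null(g1[[l]])) g1[[l]] <- g2[[l]]
    else if (!is.null(g2[[l]])) {
      g1[[l]]$dW <- g1[[l]]$dW + g2[[l]]$dW
      g1[[l]]$db <- g1[[l]]$db + g2[[l]]$db
    }
  }
  g1
}

## Adam update (beta1 = 0.9, beta2 = 0.999, eps = 1e-8), applied in place.
adamStep <- function(net, grads, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (is.null(net$adam)) {
    net$adam <- lapply(net$layers, function(ly)
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0))
  }
  net$t <- net$t + 1L
  c1 <- 1 - b1^net$t
  c2 <- 1 - b2^net$t
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    if (is.null(g)) next
    st <- net$adam[[l]]
    st$mW <- b1 * st$mW + (1 - b1) * g$dW
    st$vW <- b2 * st$vW + (1 - b2) * g$dW^2
    st$mb <- b1 * st$mb + (1 - b1) * g$db
    st$vb <- b2 * st$vb + (1 - b2) * g$db^2
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    net$adam[[l]] <- st
  }
  net
}

softmaxRows <- function(A) {
  A <- A - apply(A, 1, max)
  E <- exp(A)
  E / rowSums(E)
}
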