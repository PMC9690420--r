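## The conditional VAE-GAN backbone: encoder E, class-conditioned
## generator G, discriminator D and dropout classifier M, with joint
## alternating training under the six-term composite objective.

#' Construct an untrained network bundle
#'
#' All four networks are small dense stacks on flattened image vectors.
#' Images of any patch size are bilinearly downsampled to
#' \code{inputSize x inputSize x 3} before entering a network; the
#' generator emits images at the same internal resolution.
#'
#' @param inputSize edge length the networks see (default 16).
#' @param dZ latent dimension of the encoder (default 16).
#' @param hidden hidden-layer width shared by all networks (default 64).
#' @param dropout dropout rate of the classifier's penultimate layer,
#'   also used for Monte Carlo dropout at acquisition time (default 0.3).
#' @param lr Adam learning rate (default 2e-3).
#' @param nClasses number of classes (default 2).
#' @param seed integer seed for weight initialization.
#' @return a \linkS4class{NetworkBundle}.
#' @export
networkBundle <- function(inputSize = 16, dZ = 16, hidden = 64,
                          dropout = 0.3, lr = 2e-3, nClasses = 2L,
                          seed = 1L) {
  p <- as.integer(inputSize)^2 * 3L
  cfg <- list(inputSize = as.integer(inputSize), dZ = as.integer(dZ),
              hidden = as.integer(hidden), dropout = dropout, lr = lr,
              nClasses = as.integer(nClasses), seed = as.integer(seed))
  new("NetworkBundle",
      encoder = mlpInit(c(p, hidden, 2L * cfg$dZ), c("lrelu", "linear"),
                        deriveSeed(seed, 1L)),
      generator = mlpInit(c(cfg$dZ + cfg$nClasses, hidden, p),
                          c("lrelu", "sigmoid"), deriveSeed(seed, 2L)),
      discriminator = mlpInit(c(p, hidden, 1L), c("lrelu", "sigmoid"),
                              deriveSeed(seed, 3L)),
      classifier = mlpInit(c(p, hidden, cfg$nClasses), c("lrelu", "linear"),
                           deriveSeed(seed, 4L)),
      config = cfg, trained = FALSE)
}

## Flatten an ImageSet (or list of arrays) into the bundle's input matrix,
## downsampling to the network resolution first.
bundleInput <- function(bundle, x) {
  imgs <- if (is(x, "ImageSet")) x@images else x
  s <- bundle@config$inputSize
  t(vapply(imgs, function(a) {
    if (dim(a)[1] != s || dim(a)[2] != s) a <- resizeArray(a, s)
    as.numeric(a)
  }, numeric(s * s * 3L)))
}

labelIndex <- function(labels) {
  y <- match(labels, c("negative", "positive")) - 1L
  if (anyNA(y)) stop("labels must be 'negative' or 'positive'")
  y
}

encForwardSplit <- function(bundle, X) {
  dZ <- bundle@config$dZ
  fw <- mlpForward(bundle@encoder, X)
  mu <- fw$out[, seq_len(dZ), drop = FALSE]
  lv <- pmin(pmax(fw$out[, dZ + seq_len(dZ), drop = FALSE], -8), 8)
  list(mu = mu, logVar = lv, caches = fw$caches)
}

#' Encode images to latent codes
#'
#' @param bundle a \linkS4class{NetworkBundle}.
#' @param x an ImageSet, list of arrays, or pre-flattened matrix.
#' @param seed seed for the reparameterized draw.
#' @return list with matrices \code{mean}, \code{logVariance} and a
#'   reparameterized \code{sample} (mean + exp(logVariance/2) * eps).
#' @export
encodeImages <- function(bundle, x, seed = 1L) {
  X <- if (is.matrix(x)) x else bundleInput(bundle, x)
  enc <- encForwardSplit(bundle, X)
  eps <- withSeed(seed, matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu)))
  list(mean = enc$mu, logVariance = enc$logVar,
       sample = enc$mu + exp(0.5 * enc$logVar) * eps)
}

#' Generate images from latent codes and class labels
#'
#' @param bundle a \linkS4class{NetworkBundle}.
#' @param z latent matrix (rows = samples, dZ columns).
#' @param y zero-based class indices (1 = positive).
#' @return matrix of flattened images (rows in [0,1]).
#' @export
generateImages <- function(bundle, z, y) {
  yh <- oneHot(as.integer(y), bundle@config$nClasses)
  mlpForward(bundle@generator, cbind(z, yh))$out
}

#' Class probabilities from the classifier (dropout off)
#'
#' @param bundle a \linkS4class{NetworkBundle}.
#' @param x ImageSet, list of arrays, or matrix.
#' @return matrix of class probabilities, columns (negative, positive).
#' @export
predictProb <- function(bundle, x) {
  X <- if (is.matrix(x)) x else bundleInput(bundle, x)
  softmaxRows(mlpForward(bundle@classifier, X)$out)
}

#' Classifier penultimate features (dropout off)
#' @param bundle a \linkS4class{NetworkBundle}.
#' @param x ImageSet, list of arrays, or matrix.
#' @return matrix of penultimate-layer activations, one row per sample.
#' @export
classifierFeatures <- function(bundle, x) {
  X <- if (is.matrix(x)) x else bundleInput(bundle, x)
  mlpForward(bundle@classifier, X)$caches[[1L]]$post
}

#' Monte Carlo dropout probability stack
#'
#' Runs \code{T} stochastic forward passes of the classifier with dropout
#' active and returns the per-pass class probabilities.
#'
#' @param bundle a \linkS4class{NetworkBundle}.
#' @param x a single image array, or a pre-flattened 1 x p matrix.
#' @param T number of dropout passes (>= 1).
#' @param seed integer seed; stacks are reproducible given the seed.
#' @return a T x C matrix; each row sums to 1.
#' @export
mcDropoutStack <- function(bundle, x, T = 10L, seed = 1L) {
  if (T < 1) stop("T must be at least 1")
  X <- if (is.matrix(x)) x else bundleInput(bundle, list(x))
  rate <- bundle@config$dropout
  h <- bundle@config$hidden
  withSeed(seed, {
    out <- matrix(0, T, bundle@config$nClasses)
    for (t in seq_len(T)) {
      dm <- if (rate > 0)
        list(layer = 1L, rate = rate,
             mask = matrix(stats::rbinom(nrow(X) * h, 1L, 1 - rate), nrow(X), h))
      else NULL
      out[t, ] <- softmaxRows(mlpForward(bundle@classifier, X, dm)$out)[1L, ]
    }
    out
  })
}

## One alternating-update step on a batch. Returns updated nets plus the
## six loss-component values measured on the batch.
trainStep <- function(bundle, X, y, isLab, weights, stepSeed) {
  cfg <- bundle@config
  m <- nrow(X)
  dZ <- cfg$dZ
  C <- cfg$nClasses
  lr <- cfg$lr
  labIdx <- which(isLab)
  mL <- length(labIdx)

  ## pseudo-labels for unlabeled rows: current classifier argmax
  yAll <- y
  if (any(!isLab)) {
    pu <- predictProb(bundle, X[!isLab, , drop = FALSE])
    yAll[!isLab] <- max.col(pu) - 1L
  }

  withSeed(stepSeed, {
    ## ---- encode and generate -------------------------------------------
    enc <- encForwardSplit(bundle, X)
    eps <- matrix(stats::rnorm(m * dZ), m, dZ)
    z <- enc$mu + exp(0.5 * enc$logVar) * eps
    gIn <- cbind(z, oneHot(yAll, C))
    gFw <- mlpForward(bundle@generator, gIn)
    xre <- gFw$out
    zp <- matrix(stats::rnorm(m * dZ), m, dZ)
    yTil <- sample.int(C, m, replace = TRUE) - 1L
    gpFw <- mlpForward(bundle@generator, cbind(zp, oneHot(yTil, C)))
    xp <- gpFw$out

    ## ---- discriminator update ------------------------------------------
    dxF <- mlpForward(bundle@discriminator, X)
    dreF <- mlpForward(bundle@discriminator, xre)
    dpF <- mlpForward(bundle@discriminator, xp)
    dx <- clipProb(dxF$out[, 1L]); dre <- clipProb(dreF$out[, 1L])
    dp <- clipProb(dpF$out[, 1L])
    lD <- mean(-(log(dx) + log(1 - dre) + log(1 - dp)))
    gD <- sumGrads(
      mlpBackwardPre(bundle@discriminator, dxF$caches,
                     matrix((dx - 1) / m, m, 1))$grads,
      sumGrads(
        mlpBackwardPre(bundle@discriminator, dreF$caches,
                       matrix(dre / m, m, 1))$grads,
        mlpBackwardPre(bundle@discriminator, dpF$caches,
                       matrix(dp / m, m, 1))$grads))
    disc <- adamStep(bundle@discriminator, gD, lr)

    ## ---- classifier update (labeled rows, dropout on) ------------------
    lC <- 0
    clf <- bundle@classifier
    if (mL > 0) {
      XL <- X[labIdx, , drop = FALSE]
      yL <- y[labIdx]
      dm <- if (cfg$dropout > 0)
        list(layer = 1L, rate = cfg$dropout,
             mask = matrix(stats::rbinom(mL * cfg$hidden, 1L, 1 - cfg$dropout),
                           mL, cfg$hidden))
      else NULL
      mFw <- mlpForward(clf, XL, dm)
      probs <- softmaxRows(mFw$out)
      lC <- mean(-log(clipProb(probs[cbind(seq_len(mL), yL + 1L)])))
      dPre <- (probs - oneHot(yL, C)) / mL
      clf <- adamStep(clf, mlpBackwardPre(clf, mFw$caches, dPre)$grads, lr)
    }

    ## ---- encoder + generator update ------------------------------------
    ## KL term
    lKL <- mean(0.5 * rowSums(enc$mu^2 + exp(enc$logVar) - enc$logVar - 1))
    dMu <- enc$mu / m
    dLv <- 0.5 * (exp(enc$logVar) - 1) / m

    ## reconstruction term: pixels for all rows, features for labeled rows
    dXre <- (xre - X) / m
    lG <- mean(0.5 * rowSums((X - xre)^2))
    fdxF <- mlpForward(disc, X)
    fdreF <- mlpForward(disc, xre)
    fmxF <- mlpForward(clf, X)
    fmreF <- mlpForward(clf, xre)
    if (mL > 0) {
      fdDiff <- fdreF$caches[[1L]]$post - fdxF$caches[[1L]]$post
      fmDiff <- fmreF$caches[[1L]]$post - fmxF$caches[[1L]]$post
      fdDiff[!isLab, ] <- 0
      fmDiff[!isLab, ] <- 0
      lG <- lG + sum(0.5 * (fdDiff^2 + fmDiff^2)) / m
      dXre <- dXre +
        mlpBackward(disc, fdreF$caches, fdDiff / m, fromLayer = 1L)$dInput +
        mlpBackward(clf, fmreF$caches, fmDiff / m, fromLayer = 1L)$dInput
    }

    ## batch feature matching (discriminator view), all rows vs pseudo
    fdpF <- mlpForward(disc, xp)
    fbarR <- colMeans(fdxF$caches[[1L]]$post)
    fbarP <- colMeans(fdpF$caches[[1L]]$post)
    lGD <- 0.5 * sum((fbarR - fbarP)^2)
    dFp <- matrix(-(fbarR - fbarP) / m, m, length(fbarR), byrow = TRUE)
    dXp <- mlpBackward(disc, fdpF$caches, dFp, fromLayer = 1L)$dInput

    ## class-conditional feature matching (classifier view), labeled rows
    lGC <- 0
    if (mL > 0) {
      fmpF <- mlpForward(clf, xp)
      fR <- fmxF$caches[[1L]]$post[labIdx, , drop = FALSE]
      fP <- fmpF$caches[[1L]]$post
      dFmp <- matrix(0, m, ncol(fP))
      for (cc in seq_len(C) - 1L) {
        rIdx <- which(y[labIdx] == cc); pIdx <- which(yTil == cc)
        if (!length(rIdx) || !length(pIdx)) next  # absent class: zero term
        deltaC <- colMeans(fR[rIdx, , drop = FALSE]) -
          colMeans(fP[pIdx, , drop = FALSE])
        lGC <- lGC + sum(deltaC^2) / (2 * mL)
        dFmp[pIdx, ] <- matrix(-deltaC / (mL * length(pIdx)), length(pIdx),
                               ncol(fP), byrow = TRUE)
      }
      dXp <- dXp * weights$lambda3 +
        weights$lambda4 * mlpBackward(clf, fmpF$caches, dFmp,
                                      fromLayer = 1L)$dInput
    } else {
      dXp <- dXp * weights$lambda3
    }

    ## backprop generator: reconstruction path and pseudo path
    bgRe <- mlpBackward(bundle@generator, gFw$caches, weights$lambda2 * dXre)
    bgP <- mlpBackward(bundle@generator, gpFw$caches, dXp)
    gen <- adamStep(bundle@generator, sumGrads(bgRe$grads, bgP$grads), lr)

    ## backprop encoder through the reparameterized z
    dz <- bgRe$dInput[, seq_len(dZ), drop = FALSE]
    dMuT <- weights$lambda1 * dMu + dz
    dLvT <- weights$lambda1 * dLv + dz * eps * 0.5 * exp(0.5 * enc$logVar)
    encNet <- adamStep(bundle@encoder,
                       mlpBackward(bundle@encoder, enc$caches,
                                   cbind(dMuT, dLvT))$grads, lr)

    bundle@encoder <- encNet
    bundle@generator <- gen
    bundle@discriminator <- disc
    bundle@classifier <- clf
    list(bundle = bundle,
         losses = c(lC = lC, lD = lD, lKL = lKL, lG = lG, lGD = lGD, lGC = lGC))
  })
}

#' Jointly train the CVAE-GAN bundle
#'
#' Alternating updates per minibatch: the discriminator minimizes its
#' binary cross-entropy against true/reconstructed/pseudo samples; the
#' classifier minimizes softmax cross-entropy on labeled data only; the
#' encoder and generator minimize
#' \code{lambda1*LKL + lambda2*LG + lambda3*LGD + lambda4*LGC}. Unlabeled
#' samples contribute to the adversarial, KL and pixel-reconstruction
#' terms; label-dependent terms use labeled rows only.
#'
#' @param bundle a \linkS4class{NetworkBundle}.
#' @param labeled non-empty ImageSet with known labels.
#' @param unlabeled optional ImageSet mixed into the unsupervised terms.
#' @param weights a \code{\link{lossWeights}}.
#' @param epochs training epochs; 0 returns the bundle unchanged.
#' @param batchSize minibatch size (default 32).
#' @param seed integer seed governing shuffling, dropout, and latent draws.
#' @return list with the updated \code{bundle} and \code{trace}, a
#'   data.frame of per-epoch means of the six loss components and their
#'   weighted total.
#' @export
trainJoint <- function(bundle, labeled, unlabeled = NULL,
                       weights = lossWeights(), epochs = 10L,
                       batchSize = 32L, seed = 1L) {
  stopifnot(is(bundle, "NetworkBundle"))
  if (!is(labeled, "ImageSet") || length(labeled) == 0L)
    stop("labeled pool must be a non-empty ImageSet")
  XL <- bundleInput(bundle, labeled)
  yL <- labelIndex(labeled@manifest$label)
  XU <- if (!is.null(unlabeled) && length(unlabeled) > 0L)
    bundleInput(bundle, unlabeled) else NULL
  nL <- nrow(XL)
  trace <- data.frame()
  if (epochs >= 1L) {
    for (ep in seq_len(epochs)) {
      epSeed <- deriveSeed(seed, 100L + ep)
      ord <- withSeed(epSeed, sample.int(nL))
      starts <- seq(1L, nL, by = batchSize)
      acc <- NULL
      uPos <- 0L
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + batchSize - 1L, nL)]
        X <- XL[idx, , drop = FALSE]
        y <- yL[idx]
        isLab <- rep(TRUE, length(idx))
        if (!is.null(XU)) {
          uIdx <- ((uPos + seq_len(length(idx)) - 1L) %% nrow(XU)) + 1L
          uPos <- uPos + length(idx)
          X <- rbind(X, XU[uIdx, , drop = FALSE])
          y <- c(y, rep(0L, length(uIdx)))
          isLab <- c(isLab, rep(FALSE, length(uIdx)))
        }
        st <- trainStep(bundle, X, y, isLab, weights,
                        deriveSeed(epSeed, bi))
        bundle <- st$bundle
        acc <- if (is.null(acc)) st$losses else acc + st$losses
      }
      mean6 <- acc / length(starts)
      trace <- rbind(trace, data.frame(
        epoch = ep, t(mean6),
        total = lossTotal(mean6["lC"], mean6["lD"], mean6["lKL"],
                          mean6["lG"], mean6["lGD"], mean6["lGC"], weights)))
    }
    bundle@trained <- TRUE
  }
  rownames(trace) <- NULL
  list(bundle = bundle, trace = trace)
}
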