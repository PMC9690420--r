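## The six components of the composite training objective
##   L = LC + LD + lambda1*LKL + lambda2*LG + lambda3*LGD + lambda4*LGC
## exposed as pure closed-form functions (natural logarithm throughout;
## probabilities epsilon-clipped at 1e-7 before any log).

#' Loss weights for the composite objective
#'
#' @param lambda1 weight of the KL term (latent prior regularization);
#'   the default 0.05 balances the 768-dimensional pixel reconstruction
#'   term against the low-dimensional KL and avoids posterior collapse.
#' @param lambda2 weight of the reconstruction term.
#' @param lambda3 weight of discriminator feature matching.
#' @param lambda4 weight of class-conditional classifier feature matching.
#' @return a validated list of class \code{lossWeights}.
#' @export
lossWeights <- function(lambda1 = 0.05, lambda2 = 1, lambda3 = 1, lambda4 = 1) {
  w <- c(lambda1, lambda2, lambda3, lambda4)
  if (any(!is.finite(w)) || any(w < 0))
    stop("loss weights must be finite and non-negative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, lambda4 = lambda4),
            class = "lossWeights")
}

#' Discriminator loss
#'
#' Binary cross-entropy driving the discriminator to call the true sample
#' real and both the reconstruction and the pseudo-sample fake:
#' \code{-(log d_x + log(1 - d_xre) + log(1 - d_xp))}.
#'
#' @param dX discriminator probability on the true sample, in [0, 1].
#' @param dXre probability on the reconstructed sample.
#' @param dXp probability on the pseudo-sample.
#' @return non-negative scalar (0 at perfect discrimination).
#' @export
lossDiscriminator <- function(dX, dXre, dXp) {
  p <- c(dX, dXre, dXp)
  if (any(p < 0 | p > 1)) stop("discriminator outputs must lie in [0, 1]")
  -(log(clipProb(dX)) + log(1 - clipProb(dXre)) + log(1 - clipProb(dXp)))
}

#' Classifier loss (softmax cross-entropy)
#'
#' @param probs class-probability vector (sums to 1).
#' @param y zero-based true class index.
#' @return \code{-log probs[y]}.
#' @export
lossClassifier <- function(probs, y) {
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  if (y < 0 || y >= length(probs)) stop("class index out of range")
  -log(clipProb(probs[y + 1L]))
}

#' KL divergence of a diagonal-Gaussian posterior from N(0, I)
#'
#' Closed form \code{0.5 * sum(mean^2 + var - log var - 1)} over latent
#' dimensions.
#'
#' @param mean latent mean vector.
#' @param logVariance latent log-variance vector (same length).
#' @return non-negative scalar; 0 iff mean = 0 and var = 1.
#' @export
lossKL <- function(mean, logVariance) {
  if (length(mean) != length(logVariance)) stop("dimension mismatch")
  if (any(!is.finite(mean)) || any(!is.finite(logVariance)))
    stop("mean and logVariance must be finite")
  0.5 * sum(mean^2 + exp(logVariance) - logVariance - 1)
}

#' Reconstruction loss of the generator
#'
#' Half the summed squared differences between a true sample and its
#' reconstruction, in pixel space and in the penultimate feature spaces of
#' the discriminator and the classifier.
#'
#' @param x,xre image vectors/arrays of equal shape.
#' @param fDx,fDxre discriminator penultimate features of x and xre.
#' @param fMx,fMxre classifier penultimate features of x and xre.
#' @return non-negative scalar.
#' @export
lossGeneratorRecon <- function(x, xre, fDx = numeric(), fDxre = numeric(),
                               fMx = numeric(), fMxre = numeric()) {
  if (length(x) != length(xre) || length(fDx) != length(fDxre) ||
      length(fMx) != length(fMxre)) stop("shape mismatch")
  0.5 * (sum((x - xre)^2) + sum((fDx - fDxre)^2) + sum((fMx - fMxre)^2))
}

#' Batch feature-matching loss in discriminator space
#'
#' Half the squared distance between batch-mean discriminator features of
#' real and pseudo samples.
#'
#' @param fDReal,fDPseudo m x dim feature matrices (equal batch size m).
#' @return non-negative scalar.
#' @export
lossFeatureMatchingD <- function(fDReal, fDPseudo) {
  fDReal <- as.matrix(fDReal); fDPseudo <- as.matrix(fDPseudo)
  if (nrow(fDReal) == 0L || nrow(fDPseudo) == 0L) stop("empty batch")
  if (nrow(fDReal) != nrow(fDPseudo)) stop("batch sizes differ")
  0.5 * sum((colMeans(fDReal) - colMeans(fDPseudo))^2)
}

#' Class-conditional feature-matching loss in classifier space
#'
#' Matches the per-class mean classifier features between real and pseudo
#' batches, summed over classes and normalized by the batch size m:
#' \code{(1 / (2m)) * sum_c || fbar_c(x) - fbar_c(xp) ||^2}. Classes
#' absent on either side contribute a zero mean; matching class centers
#' per class (rather than their aggregate) is what ties the generator's
#' label input to class-specific image content.
#'
#' @param fMRealMeans,fMPseudoMeans lists (or matrices with one row per
#'   class) of per-class mean feature vectors; classes aligned.
#' @param m batch size used for normalization.
#' @return non-negative scalar.
#' @export
lossFeatureMatchingC <- function(fMRealMeans, fMPseudoMeans, m = 1) {
  toMat <- function(x) if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  R <- toMat(fMRealMeans); P <- toMat(fMPseudoMeans)
  if (!all(dim(R) == dim(P))) stop("class sets/dimensions differ")
  if (m <= 0) stop("m must be positive")
  sum((R - P)^2) / (2 * m)
}

#' Composite training loss
#'
#' \code{LC + LD + lambda1*LKL + lambda2*LG + lambda3*LGD + lambda4*LGC}.
#'
#' @param lC,lD,lKL,lG,lGD,lGC the six finite component values.
#' @param weights a \code{\link{lossWeights}} object.
#' @return weighted sum.
#' @export
lossTotal <- function(lC, lD, lKL = 0, lG = 0, lGD = 0, lGC = 0,
                      weights = lossWeights()) {
  comps <- c(lC, lD, lKL, lG, lGD, lGC)
  if (any(!is.finite(comps))) stop("all loss components must be finite")
  lC + lD + weights$lambda1 * lKL + weights$lambda2 * lG +
    weights$lambda3 * lGD + weights$lambda4 * lGC
}
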