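## Synthetic two-class histology-like patch generator and the preprocessing
## pipeline around it: invalid-image screening, bilinear resize, 8-fold
## dihedral augmentation, additive-noise perturbation, stratified splitting.

#' Configuration for the synthetic patch generator
#'
#' The generator emulates a binary-class histopathology patch corpus:
#' pinkish eosin-like background with dark nucleus-like blobs whose density
#' differs between the two classes. \code{textureContrast} controls how far
#' apart the class-conditional blob densities are (1 = maximally distinct,
#' near 0 = almost indistinguishable). A fraction of deliberately blank,
#' near-zero-variance images can be injected to exercise the screening
#' step.
#'
#' @param nPositive,nNegative number of samples per class; their default
#'   ratio (3904:2922, about 57/43) mirrors a typical mildly imbalanced
#'   tumor-patch corpus.
#' @param patchSize square patch edge length in pixels (>= 8); default 64
#'   keeps desk-scale experiments fast (200 reproduces full-size patches).
#' @param textureContrast real in (0, 1]; class separation of the blob
#'   density statistic.
#' @param invalidFraction real in [0, 1); fraction (of nPositive+nNegative)
#'   of blank images appended with label "unknown".
#' @param seed integer RNG seed; regeneration with the same configuration
#'   is bit-identical.
#' @return a validated list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nPositive = 3904, nNegative = 2922,
                            patchSize = 64, textureContrast = 0.7,
                            invalidFraction = 0, seed = 1L) {
  if (nPositive <= 0 || nNegative <= 0)
    stop("nPositive and nNegative must both be positive")
  if (patchSize < 8) stop("patchSize must be at least 8")
  if (textureContrast <= 0 || textureContrast > 1)
    stop("textureContrast must lie in (0, 1]")
  if (invalidFraction < 0 || invalidFraction >= 1)
    stop("invalidFraction must lie in [0, 1)")
  structure(list(nPositive = as.integer(nPositive),
                 nNegative = as.integer(nNegative),
                 patchSize = as.integer(patchSize),
                 textureContrast = textureContrast,
                 invalidFraction = invalidFraction,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

## Draw one patch: background + nBlobs soft dark blobs.
drawPatch <- function(p, nBlobs, gx, gy) {
  bg <- c(0.88, 0.72, 0.82)                      # eosin-like background
  nucleus <- c(0.38, 0.22, 0.52)                 # hematoxylin-like blobs
  canvas <- array(rep(bg, each = p * p), dim = c(p, p, 3))
  canvas <- canvas + array(stats::rnorm(p * p * 3, 0, 0.02), dim = c(p, p, 3))
  if (nBlobs > 0) {
    for (b in seq_len(nBlobs)) {
      cx <- stats::runif(1, 1, p)
      cy <- stats::runif(1, 1, p)
      r <- p / 10 * stats::runif(1, 0.6, 1.4)
      a <- stats::runif(1, 0.6, 0.95)
      mask <- a * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * r^2))
      for (ch in 1:3)
        canvas[, , ch] <- canvas[, , ch] * (1 - mask) + nucleus[ch] * mask
    }
  }
  clip01(canvas)
}

#' Generate a synthetic two-class image dataset
#'
#' Positive and negative patches differ in nucleus-blob density: the
#' per-class Poisson blob rates are \code{d0 * (1 + 0.85 * contrast)} and
#' \code{d0 * (1 - 0.85 * contrast)} with a base density d0 of 7 blobs per
#' patch (blob radius scales with patch size, so the texture statistic is
#' resolution-invariant). Blank invalid images, if requested, are appended
#' with label "unknown".
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return an \linkS4class{ImageSet} of
#'   \code{nPositive + nNegative (+ injected invalid)} samples.
#' @examples
#' ds <- generateDataset(syntheticConfig(nPositive = 20, nNegative = 15,
#'                                       patchSize = 16))
#' length(ds)   # 35
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  p <- config$patchSize
  withSeed(config$seed, {
    gx <- matrix(seq_len(p), p, p, byrow = FALSE)  # row coordinate
    gy <- matrix(seq_len(p), p, p, byrow = TRUE)   # column coordinate
    d0 <- 7   # blob radius scales with p, so density is size-invariant
    lamPos <- d0 * (1 + 0.85 * config$textureContrast)
    lamNeg <- d0 * (1 - 0.85 * config$textureContrast)
    nPos <- config$nPositive
    nNeg <- config$nNegative
    nInv <- round(config$invalidFraction * (nPos + nNeg))
    images <- vector("list", nPos + nNeg + nInv)
    labels <- character(nPos + nNeg + nInv)
    ids <- character(nPos + nNeg + nInv)
    k <- 0L
    for (i in seq_len(nPos)) {
      k <- k + 1L
      images[[k]] <- drawPatch(p, stats::rpois(1, lamPos), gx, gy)
      labels[k] <- "positive"; ids[k] <- sprintf("pos%05d", i)
    }
    for (i in seq_len(nNeg)) {
      k <- k + 1L
      images[[k]] <- drawPatch(p, stats::rpois(1, lamNeg), gx, gy)
      labels[k] <- "negative"; ids[k] <- sprintf("neg%05d", i)
    }
    for (i in seq_len(nInv)) {
      k <- k + 1L
      images[[k]] <- array(0.95, dim = c(p, p, 3))  # blank, zero variance
      labels[k] <- "unknown"; ids[k] <- sprintf("inv%05d", i)
    }
    ImageSet(images, ids = ids, labels = labels)
  })
}

#' Mean-texture feature matrix of an ImageSet
#'
#' Per-sample summary features (per-channel means, overall standard
#' deviation, fraction of dark pixels) used by diagnostic probes of class
#' separability.
#' @param x an ImageSet
#' @return numeric matrix, one row per sample.
#' @export
textureFeatures <- function(x) {
  t(vapply(x@images, function(a) {
    c(meanR = mean(a[, , 1]), meanG = mean(a[, , 2]), meanB = mean(a[, , 3]),
      sd = stats::sd(a), darkFrac = mean(a[, , 1] < 0.6))
  }, numeric(5)))
}

#' Screen out invalid (blank or saturated) images
#'
#' A programmatic surrogate for manual quality screening of histopathology
#' patches: an image is rejected when its largest per-channel intensity
#' variance falls below \code{varianceFloor} (blank / tissue-free patches)
#' or when the fraction of saturated pixels (mean intensity >= 0.98)
#' exceeds \code{saturationCeiling} (washed-out patches).
#'
#' @param x an ImageSet.
#' @param varianceFloor,saturationCeiling non-negative thresholds.
#' @return list with elements \code{valid} and \code{rejected}; together
#'   they partition the input.
#' @export
screenInvalid <- function(x, varianceFloor = 1e-4, saturationCeiling = 0.5) {
  if (varianceFloor < 0 || saturationCeiling < 0)
    stop("thresholds must be non-negative")
  keep <- vapply(x@images, function(a) {
    v <- max(apply(a, 3, stats::var))
    satFrac <- mean((a[, , 1] + a[, , 2] + a[, , 3]) / 3 >= 0.98)
    v >= varianceFloor && satFrac <= saturationCeiling
  }, logical(1))
  list(valid = x[which(keep)], rejected = x[which(!keep)])
}

## Bilinear resize of a single h x w x 3 array via EBImage.
resizeArray <- function(a, target) {
  if (target < 8) stop("target size must be at least 8")
  if (dim(a)[1] == target && dim(a)[2] == target) return(a)
  img <- EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(img, w = target, h = target)  # bilinear filter
  clip01(aperm(EBImage::imageData(out), c(2, 1, 3)))
}

#' Resize images to a square target size (bilinear)
#'
#' @param x an ImageSet or a single height x width x 3 array.
#' @param target target edge length in pixels (>= 8).
#' @return object of the same kind with all images target x target.
#' @export
resizeImage <- function(x, target) {
  if (is.array(x)) return(resizeArray(x, target))
  stopifnot(is(x, "ImageSet"))
  x@images <- lapply(x@images, resizeArray, target = target)
  x
}

## Exact 90-degree clockwise rotation, per channel.
rot90cw <- function(a) {
  out <- array(0, dim = c(dim(a)[2], dim(a)[1], dim(a)[3]))
  for (ch in seq_len(dim(a)[3])) out[, , ch] <- t(a[rev(seq_len(dim(a)[1])), , ch])
  out
}

flipH <- function(a) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]

## The 8 dihedral-group transforms of the square, as exact permutations.
d4Transforms <- function() {
  r0 <- function(a) a
  r90 <- rot90cw
  r180 <- function(a) rot90cw(rot90cw(a))
  r270 <- function(a) rot90cw(rot90cw(rot90cw(a)))
  list(orig = r0, r90 = r90, r180 = r180, r270 = r270,
       fh = function(a) flipH(a),
       r90fh = function(a) flipH(r90(a)),
       r180fh = function(a) flipH(r180(a)),
       r270fh = function(a) flipH(r270(a)))
}

#' Eight-fold dihedral (D4) augmentation
#'
#' Expands the dataset by the full orbit of the square's symmetry group:
#' rotations by 0/90/180/270 degrees, each with and without a horizontal
#' flip. The vertical flip is contained in this set as rotation composed
#' with horizontal flip, so the orbit realizes an exact 8x expansion.
#' Pixel-identical variants of symmetric images are retained (no
#' deduplication). Non-identity variants carry provenance "augmented".
#'
#' @param x a non-empty ImageSet.
#' @return an ImageSet with \code{8 * length(x)} samples; labels and splits
#'   are inherited.
#' @export
augmentD4 <- function(x) {
  stopifnot(is(x, "ImageSet"))
  n <- length(x)
  if (n == 0L) return(x)
  tfs <- d4Transforms()
  variants <- names(tfs)
  images <- vector("list", 8L * n)
  man <- x@manifest[rep(seq_len(n), each = 8L), , drop = FALSE]
  suffix <- rep(variants, times = n)
  man$id <- ifelse(suffix == "orig", man$id, paste0(man$id, "_", suffix))
  man$provenance <- ifelse(suffix == "orig", man$provenance, "augmented")
  rownames(man) <- NULL
  k <- 0L
  for (i in seq_len(n)) {
    a <- x@images[[i]]
    for (v in variants) {
      k <- k + 1L
      images[[k]] <- tfs[[v]](a)
    }
  }
  new("ImageSet", images = images, manifest = man)
}

#' Add Gaussian noise to a random subset of images
#'
#' Exactly \code{round(fraction * n)} samples receive zero-mean Gaussian
#' pixel noise with standard deviation \code{sigma}, in place (the sample
#' count is unchanged); results are clipped back to [0, 1].
#'
#' @param x an ImageSet.
#' @param fraction real in [0, 1]: fraction of samples to perturb.
#' @param sigma noise standard deviation (>= 0), on the [0,1] pixel scale.
#' @param seed integer seed; the perturbed subset and the noise are
#'   deterministic given the seed.
#' @return an ImageSet of identical size and manifest.
#' @export
addNoiseSubset <- function(x, fraction, sigma = 0.05, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (sigma < 0) stop("sigma must be non-negative")
  n <- length(x)
  nMod <- round(fraction * n)
  if (nMod == 0L || sigma == 0) return(x)
  withSeed(seed, {
    idx <- sample.int(n, nMod)
    for (i in idx) {
      a <- x@images[[i]]
      x@images[[i]] <- clip01(a + array(stats::rnorm(length(a), 0, sigma),
                                        dim = dim(a)))
    }
  })
  x
}

#' Stratified train/test split
#'
#' Assigns each sample a split so that, within every class, the train
#' fraction is within one sample of \code{trainRatio}.
#'
#' @param x an ImageSet whose samples all carry a known label.
#' @param trainRatio real in (0, 1).
#' @param seed integer seed.
#' @return the ImageSet with the manifest's split column filled in.
#' @export
stratifiedSplit <- function(x, trainRatio = 0.7, seed = 1L) {
  if (trainRatio <= 0 || trainRatio >= 1) stop("trainRatio must lie in (0, 1)")
  labs <- x@manifest$label
  if (any(labs == "unknown"))
    stop("cannot stratify on unlabeled samples; screen or label them first")
  for (cl in c("negative", "positive"))
    if (sum(labs == cl) == 0L) stop("class '", cl, "' has no samples")
  split <- rep("test", length(x))
  withSeed(seed, {
    for (cl in unique(labs)) {
      idx <- which(labs == cl)
      nTrain <- round(trainRatio * length(idx))
      split[sample(idx, nTrain)] <- "train"
    }
  })
  x@manifest$split <- split
  x
}
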