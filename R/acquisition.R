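## Acquisition scoring: BALD mutual information via MC dropout, baseline
## uncertainty scores, centroid-distance diversity in latent space, and
## the min-max-scaled combined score.

#' Acquisition configuration
#'
#' @param T Monte Carlo dropout rounds (default 10).
#' @param k truncation coefficient: number of nearest class centroids kept
#'   in the diversity score (default 2, i.e. all classes of a binary task).
#' @param theta trade-off in [0, 1]: weight on scaled uncertainty versus
#'   scaled diversity (default 0.5, equal weighting).
#' @param poolSize candidates drawn from the unlabeled pool per iteration.
#' @param nSelect samples selected per iteration (<= poolSize).
#' @param seed integer seed.
#' @return a validated list of class \code{acquisitionConfig}.
#' @export
acquisitionConfig <- function(T = 10L, k = 2L, theta = 0.5,
                              poolSize = 500L, nSelect = 100L, seed = 1L) {
  if (T < 1) stop("T must be at least 1")
  if (k < 1) stop("k must be at least 1")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (nSelect > poolSize) stop("nSelect must not exceed poolSize")
  structure(list(T = as.integer(T), k = as.integer(k), theta = theta,
                 poolSize = as.integer(poolSize),
                 nSelect = as.integer(nSelect), seed = as.integer(seed)),
            class = "acquisitionConfig")
}

checkRows1 <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-6))
    stop("each probability row must sum to 1")
}

#' BALD uncertainty from an MC-dropout probability stack
#'
#' Mutual information between the prediction and the model parameters,
#' approximated as the entropy of the mean prediction minus the mean
#' per-pass entropy:
#' \code{H(mean_t p_t) - (1/T) sum_t H(p_t)} (natural log).
#'
#' @param probStack T x C matrix; each row a probability vector.
#' @return non-negative scalar (0 when all passes agree).
#' @export
baldUncertainty <- function(probStack) {
  probStack <- rbind(probStack)
  checkRows1(probStack)
  pBar <- colMeans(probStack)
  max(shannonEntropy(pBar) - mean(apply(probStack, 1, shannonEntropy)), 0)
}

#' Predictive-entropy score
#' @param probs probability vector over classes (sums to 1).
#' @return Shannon entropy (natural log), >= 0.
#' @export
entropyScore <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  shannonEntropy(probs)
}

#' Least-confidence score
#' @param probs probability vector over classes (sums to 1).
#' @return \code{1 - max(probs)}, >= 0.
#' @export
confidenceScore <- function(probs) {
  if (abs(sum(probs) - 1) > 1e-6) stop("probs must sum to 1")
  1 - max(probs)
}

#' Per-class centroids of labeled latent codes
#'
#' @param latents n x dZ matrix of latent vectors (the encoder means).
#' @param classes per-row class labels (any type; levels sorted).
#' @return list with \code{centroids} (class x dZ matrix, rownames = class)
#'   and \code{counts}.
#' @export
classCentroids <- function(latents, classes) {
  latents <- as.matrix(latents)
  lv <- sort(unique(as.character(classes)))
  cents <- matrix(0, length(lv), ncol(latents), dimnames = list(lv, NULL))
  counts <- integer(length(lv))
  for (i in seq_along(lv)) {
    idx <- which(as.character(classes) == lv[i])
    if (!length(idx)) stop("class '", lv[i], "' has no members")
    cents[i, ] <- colMeans(latents[idx, , drop = FALSE])
    counts[i] <- length(idx)
  }
  list(centroids = cents, counts = stats::setNames(counts, lv))
}

#' Euclidean distances from a latent vector to each class centroid
#'
#' @param z latent vector (length dZ).
#' @param centroids result of \code{\link{classCentroids}} (or a plain
#'   class x dZ matrix).
#' @return named numeric vector of L2 distances, in class order.
#' @export
centroidDistances <- function(z, centroids) {
  M <- if (is.list(centroids)) centroids$centroids else centroids
  if (length(z) != ncol(M)) stop("latent dimension mismatch")
  apply(M, 1, function(cc) sqrt(sum((z - cc)^2)))
}

#' Diversity score: entropy of softmaxed z-scored centroid distances
#'
#' Distances are sorted ascending and truncated to the \code{k} nearest
#' classes, z-scored with the population standard deviation (a
#' zero-variance vector maps to all-zero z-scores, hence a uniform
#' softmax), softmaxed, and summarized by Shannon entropy. The score is
#' largest (\code{log k}) when the sample is equidistant from the kept
#' centroids, i.e. in the disagreement region between classes, and 0 for
#' k = 1.
#'
#' @param distances per-class distance vector.
#' @param k truncation coefficient, 1 <= k <= length(distances).
#' @return scalar in [0, log k].
#' @export
diversityScore <- function(distances, k = length(distances)) {
  if (k < 1 || k > length(distances)) stop("k out of range")
  d <- sort(distances)[seq_len(k)]
  if (k == 1L) return(0)
  sdPop <- sqrt(mean((d - mean(d))^2))
  zs <- if (sdPop == 0) rep(0, k) else (d - mean(d)) / sdPop
  shannonEntropy(softmaxVec(zs))
}

#' Min-max scaling to [0, 1]
#'
#' \code{(v - min) / (max - min)}; a constant vector maps to all zeros.
#'
#' @param values non-empty numeric vector.
#' @return vector in [0, 1].
#' @export
minmaxScale <- function(values) {
  if (!length(values)) stop("empty input")
  r <- range(values)
  if (r[1] == r[2]) return(rep(0, length(values)))
  (values - r[1]) / (r[2] - r[1])
}

#' Combined acquisition score
#'
#' \code{theta * uncScaled + (1 - theta) * divScaled}: theta = 1 recovers
#' the pure uncertainty ranking, theta = 0 the pure diversity ranking.
#'
#' @param uncScaled,divScaled min-max-scaled score vectors of equal length.
#' @param theta trade-off coefficient in [0, 1].
#' @return combined score vector.
#' @export
combinedScore <- function(uncScaled, divScaled, theta = 0.5) {
  if (length(uncScaled) != length(divScaled)) stop("length mismatch")
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  theta * uncScaled + (1 - theta) * divScaled
}

#' Select the n highest-scoring candidates
#'
#' Ties are broken by lexicographic sample id, making selection
#' deterministic.
#'
#' @param scores data.frame with columns \code{sample_id} and
#'   \code{combined} (as produced by \code{\link{scorePool}}), or a named
#'   numeric vector.
#' @param nSelect number of ids to return (<= number of candidates).
#' @return character vector of the selected ids, highest score first.
#' @export
rankAndSelect <- function(scores, nSelect) {
  if (is.numeric(scores))
    scores <- data.frame(sample_id = names(scores), combined = unname(scores),
                         stringsAsFactors = FALSE)
  if (nSelect > nrow(scores)) stop("nSelect exceeds the candidate pool")
  ord <- order(-scores$combined, scores$sample_id)
  scores$sample_id[ord][seq_len(nSelect)]
}

#' Score a candidate pool under a selection strategy
#'
#' Computes per-candidate ScoreRecords. For the \code{combined} strategy
#' this is BALD uncertainty (MC dropout, \code{T} rounds), the
#' centroid-distance diversity score against the labeled pool's per-class
#' latent centroids, min-max scaling of both, and their theta-weighted
#' combination. The \code{bald}/\code{gan_bald}, \code{entropy},
#' \code{confidence} and \code{random} strategies fill the combined column
#' with their single score.
#'
#' @param bundle a trained \linkS4class{NetworkBundle}.
#' @param candidates ImageSet of unlabeled candidates.
#' @param labeled ImageSet of the current labeled pool (needed for the
#'   diversity centroids).
#' @param config an \code{\link{acquisitionConfig}}.
#' @param strategy one of "combined", "bald", "gan_bald", "entropy",
#'   "confidence", "random".
#' @param seed integer seed (MC dropout masks, random strategy).
#' @return data.frame with columns sample_id, uncertainty, diversity,
#'   unc_scaled, div_scaled, combined.
#' @export
scorePool <- function(bundle, candidates, labeled, config = acquisitionConfig(),
                      strategy = "combined", seed = 1L) {
  strategy <- match.arg(strategy, c("combined", "bald", "gan_bald",
                                    "entropy", "confidence", "random"))
  n <- length(candidates)
  ids <- sampleIds(candidates)
  X <- bundleInput(bundle, candidates)
  unc <- numeric(n)
  div <- numeric(n)
  if (strategy %in% c("combined", "bald", "gan_bald")) {
    for (i in seq_len(n))
      unc[i] <- baldUncertainty(
        mcDropoutStack(bundle, X[i, , drop = FALSE], T = config$T,
                       seed = deriveSeed(seed, i)))
  } else if (strategy == "entropy") {
    P <- predictProb(bundle, X)
    unc <- apply(P, 1, entropyScore)
  } else if (strategy == "confidence") {
    P <- predictProb(bundle, X)
    unc <- apply(P, 1, confidenceScore)
  } else if (strategy == "random") {
    unc <- withSeed(seed, stats::runif(n))
  }
  if (strategy == "combined") {
    zLab <- encodeImages(bundle, labeled, seed = deriveSeed(seed, 0L))$mean
    cents <- classCentroids(zLab, labeled@manifest$label)
    zCand <- encForwardSplit(bundle, X)$mu
    for (i in seq_len(n))
      div[i] <- diversityScore(centroidDistances(zCand[i, ], cents),
                               k = min(config$k, nrow(cents$centroids)))
    uncS <- minmaxScale(unc)
    divS <- minmaxScale(div)
    comb <- combinedScore(uncS, divS, config$theta)
  } else {
    uncS <- minmaxScale(unc)
    divS <- rep(0, n)
    comb <- unc
  }
  data.frame(sample_id = ids, uncertainty = unc, diversity = div,
             unc_scaled = uncS, div_scaled = divS, combined = comb,
             stringsAsFactors = FALSE)
}
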