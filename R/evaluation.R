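## Metrics, learning curves, convergence fractions, strategy comparisons
## and classical-MDS embedding of classifier features.

#' Confusion table
#'
#' @param tp,fp,fn,tn non-negative counts (true/false positive/negative).
#' @return a list of class \code{confusionTable}.
#' @export
confusionTable <- function(tp, fp, fn, tn) {
  v <- c(tp, fp, fn, tn)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
            class = "confusionTable")
}

#' Accuracy, recall and precision from a confusion table
#'
#' Positive = tumor-positive, the class whose misses matter most
#' clinically, so recall is reported for it. Undefined ratios (zero
#' denominator) are returned as NA rather than silently as 0.
#'
#' @param table a \code{\link{confusionTable}}.
#' @return named numeric vector (accuracy, recall, precision); undefined
#'   entries are NA.
#' @export
confusionMetrics <- function(table) {
  stopifnot(inherits(table, "confusionTable"))
  total <- table$tp + table$fp + table$fn + table$tn
  if (total <= 0) stop("confusion table is empty")
  c(accuracy = (table$tp + table$tn) / total,
    recall = if (table$tp + table$fn > 0) table$tp / (table$tp + table$fn)
             else NA_real_,
    precision = if (table$tp + table$fp > 0) table$tp / (table$tp + table$fp)
                else NA_real_)
}

#' Area under the ROC curve (rank formulation)
#'
#' Mann-Whitney statistic: the probability that a random positive outscores
#' a random negative, ties counting one half.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels binary labels (0/1, logical, or "negative"/"positive").
#' @return AUC in [0, 1].
#' @export
aucScore <- function(scores, labels) {
  if (is.character(labels)) labels <- as.integer(labels == "positive")
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  r <- rank(scores)   # mean ranks handle ties with the 1/2 convention
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Build a learning curve from run history
#'
#' Curve points are keyed by labeled fraction, counting only
#' oracle-labeled originals (reconstructions cost no annotation and are
#' excluded from both numerator and denominator).
#'
#' @param history data.frame as returned by \code{runHistory}, with
#'   columns labeled_fraction and the metric.
#' @param metric metric column name ("accuracy", "recall" or "auc").
#' @param reference optional full-training reference value.
#' @return a list of class \code{learningCurve} with data.frame
#'   \code{points} (fraction, value) and \code{reference}.
#' @export
buildLearningCurve <- function(history, metric = "accuracy",
                               reference = NULL) {
  if (!nrow(history)) stop("history has no records")
  if (!metric %in% colnames(history)) stop("unknown metric: ", metric)
  pts <- data.frame(fraction = history$labeled_fraction,
                    value = history[[metric]])
  pts <- pts[order(pts$fraction), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, metric = metric, reference = reference),
            class = "learningCurve")
}

#' Smallest labeled fraction matching full-training performance
#'
#' @param curve a \code{\link{buildLearningCurve}} result with a reference.
#' @param tolerance metric slack below the reference still counted as
#'   converged.
#' @return the smallest fraction whose metric is at least
#'   \code{reference - tolerance}; 1.0 if never reached.
#' @export
convergenceFraction <- function(curve, tolerance = 0.005) {
  stopifnot(inherits(curve, "learningCurve"))
  if (is.null(curve$reference)) stop("curve has no reference value")
  ok <- which(curve$points$value >= curve$reference - tolerance)
  if (!length(ok)) return(1.0)
  curve$points$fraction[min(ok)]
}

#' Percent-increase comparison of strategies over a baseline
#'
#' Per strategy, \code{100 * (v - v_base) / v_base}; the reported average
#' is the mean of the listed strategies' individual increases.
#'
#' @param values named numeric vector of a final metric per strategy.
#' @param baseline name of the baseline strategy (must be present).
#' @return data.frame (strategy, value, pct_increase) with the baseline
#'   first; attribute \code{mean_increase} holds the mean percent increase
#'   of the non-baseline strategies.
#' @export
strategyComparison <- function(values, baseline = "Random") {
  if (!baseline %in% names(values)) stop("baseline strategy not present")
  vBase <- values[[baseline]]
  if (vBase == 0) stop("baseline value is zero; percent increase undefined")
  others <- setdiff(names(values), baseline)
  inc <- 100 * (values[others] - vBase) / vBase
  out <- data.frame(strategy = c(baseline, others),
                    value = c(vBase, unname(values[others])),
                    pct_increase = c(0, unname(inc)),
                    stringsAsFactors = FALSE)
  attr(out, "mean_increase") <- mean(inc)
  out
}

#' Classical MDS embedding of feature vectors
#'
#' Torgerson scaling (double-centered Gram eigendecomposition) of the
#' pairwise Euclidean distances, as used to visualize the classifier's
#' penultimate-layer features. The Spearman correlation between input and
#' output pairwise distances is attached as a fidelity diagnostic.
#'
#' @param features n x d numeric matrix.
#' @param targetDim embedding dimension (default 2); requires
#'   \code{n >= targetDim + 1}.
#' @return n x targetDim coordinate matrix with attribute
#'   \code{distance_spearman}.
#' @export
mdsEmbed <- function(features, targetDim = 2L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < targetDim + 1L) stop("need at least targetDim + 1 points")
  d <- stats::dist(features)
  coords <- stats::cmdscale(d, k = targetDim)
  if (ncol(coords) < targetDim)   # degenerate geometry: pad zero columns
    coords <- cbind(coords, matrix(0, n, targetDim - ncol(coords)))
  rho <- suppressWarnings(
    stats::cor(as.numeric(d), as.numeric(stats::dist(coords)),
               method = "spearman"))
  attr(coords, "distance_spearman") <- rho
  coords
}
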