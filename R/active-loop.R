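## The iterative select/label/reconstruct/retrain loop with a simulated
## oracle and pluggable acquisition strategies.

#' Simulated labeling oracle
#'
#' Stands in for the human expert: answers label queries from the
#' generator's ground truth and audits how many labels were requested.
#' Labels of unqueried samples are never read by the loop.
#'
#' @param truth an ImageSet whose manifest labels are the ground truth, or
#'   a named character vector id -> label.
#' @return an object of class \code{simulatedOracle}.
#' @export
simulatedOracle <- function(truth) {
  if (is(truth, "ImageSet"))
    truth <- stats::setNames(truth@manifest$label, truth@manifest$id)
  env <- new.env(parent = emptyenv())
  env$truth <- truth
  env$count <- 0L
  structure(list(env = env), class = "simulatedOracle")
}

#' Query labels from the oracle
#' @param oracle a \code{\link{simulatedOracle}}.
#' @param ids sample ids to label.
#' @return character vector of labels; the oracle's query count grows by
#'   \code{length(ids)}.
#' @export
queryLabel <- function(oracle, ids) {
  labs <- oracle$env$truth[ids]
  if (anyNA(labs)) stop("oracle has no label for: ",
                        paste(ids[is.na(labs)], collapse = ", "))
  oracle$env$count <- oracle$env$count + length(ids)
  unname(labs)
}

#' Number of labels the oracle has been asked for
#' @param oracle a \code{\link{simulatedOracle}}.
#' @export
oracleCount <- function(oracle) oracle$env$count

#' Loop state constructor
#'
#' @param labeled ImageSet forming the initial labeled pool D_L.
#' @param unlabeled ImageSet forming the unlabeled pool D_U; ids must be
#'   disjoint from the labeled pool.
#' @return list of class \code{loopState} with elements labeled, unlabeled,
#'   iteration.
#' @export
loopState <- function(labeled, unlabeled) {
  if (length(intersect(sampleIds(labeled), sampleIds(unlabeled))))
    stop("labeled and unlabeled pools must be id-disjoint")
  structure(list(labeled = labeled, unlabeled = unlabeled, iteration = 0L),
            class = "loopState")
}

#' Randomly draw candidate ids from the unlabeled pool
#'
#' @param state a \code{\link{loopState}}.
#' @param poolSize number of candidates; capped at the pool size.
#' @param seed integer seed.
#' @return character vector of candidate ids (empty if D_U is empty,
#'   signalling loop termination).
#' @export
samplePool <- function(state, poolSize, seed = 1L) {
  ids <- sampleIds(state$unlabeled)
  if (!length(ids)) return(character())
  n <- min(poolSize, length(ids))
  withSeed(seed, sample(ids, n))
}

#' Reconstruct selected samples through the generator
#'
#' Encodes each selected sample and decodes it conditioned on its oracle
#' label, yielding a noisy twin that joins the labeled pool at no
#' annotation cost. Reconstructions are upsampled back to the original
#' patch size and carry provenance "reconstructed" and fresh ids
#' (\code{<id>_re}).
#'
#' @param bundle a trained \linkS4class{NetworkBundle}.
#' @param selected ImageSet of the selected samples.
#' @param labels oracle labels for the selected samples.
#' @param seed integer seed for the latent draw.
#' @return an ImageSet of reconstructions.
#' @export
reconstructSelected <- function(bundle, selected, labels, seed = 1L) {
  if (!bundle@trained) stop("bundle must be trained before reconstruction")
  n <- length(selected)
  stopifnot(length(labels) == n)
  z <- encodeImages(bundle, selected, seed = seed)$sample
  out <- generateImages(bundle, z, labelIndex(labels))
  s <- bundle@config$inputSize
  targetDim <- dim(selected@images[[1L]])[1]
  imgs <- lapply(seq_len(n), function(i) {
    a <- array(clip01(out[i, ]), dim = c(s, s, 3))
    if (targetDim != s) a <- resizeArray(a, targetDim)
    a
  })
  ImageSet(imgs, ids = paste0(sampleIds(selected), "_re"),
           labels = labels, splits = selected@manifest$split,
           provenance = "reconstructed")
}

#' Move selected samples (and reconstructions) into the labeled pool
#'
#' Implements the labeled-pool update D_L <- D_L U {(x*, y*), (xre*, y*)}:
#' selected ids leave D_U and join D_L with their oracle labels;
#' reconstructions, if given, join D_L under their own ids. Pool
#' disjointness is preserved.
#'
#' @param state a \code{\link{loopState}}.
#' @param selectedIds ids currently in the unlabeled pool.
#' @param labels oracle labels for \code{selectedIds}.
#' @param reconstructions optional ImageSet from
#'   \code{\link{reconstructSelected}}.
#' @return the updated \code{loopState}.
#' @export
incorporate <- function(state, selectedIds, labels, reconstructions = NULL) {
  if (!length(selectedIds)) return(state)
  pos <- match(selectedIds, sampleIds(state$unlabeled))
  if (anyNA(pos)) stop("id(s) not in the unlabeled pool: ",
                       paste(selectedIds[is.na(pos)], collapse = ", "))
  moved <- state$unlabeled[pos]
  moved@manifest$label <- as.character(labels)
  state$unlabeled <- state$unlabeled[-pos]
  state$labeled <- c(state$labeled, moved)
  if (!is.null(reconstructions) && length(reconstructions))
    state$labeled <- c(state$labeled, reconstructions)
  state
}

#' Active-learning loop configuration
#'
#' @param strategy acquisition arm: "combined" (BALD + diversity +
#'   reconstruction), "gan_bald" (BALD + reconstruction), or the
#'   non-generative baselines "bald", "entropy", "confidence", "random"
#'   (selected originals only).
#' @param acquisition an \code{\link{acquisitionConfig}}.
#' @param maxIterations maximum loop iterations (>= 0... 0 trains once and
#'   returns an empty history).
#' @param labelBudget total oracle queries permitted (default unlimited).
#' @param initialFraction stratified fraction of the train split used as
#'   the initial labeled pool (default 0.10).
#' @param initialEpochs epochs of the initial joint training.
#' @param retrainEpochs warm-start epochs after each incorporation.
#' @param warmStart continue from current parameters when retraining
#'   (FALSE restarts from fresh initialization each iteration).
#' @param stopTolerance stop once test accuracy reaches
#'   \code{reference - stopTolerance}, when a reference is supplied.
#' @param weights a \code{\link{lossWeights}}.
#' @param batchSize minibatch size for training.
#' @param seed master seed; every random draw of the run derives from it.
#' @return a validated list of class \code{loopConfig}.
#' @export
loopConfig <- function(strategy = "combined",
                       acquisition = acquisitionConfig(),
                       maxIterations = 10L, labelBudget = Inf,
                       initialFraction = 0.1, initialEpochs = 30L,
                       retrainEpochs = 6L, warmStart = TRUE,
                       stopTolerance = 0.005, weights = lossWeights(),
                       batchSize = 32L, seed = 1L) {
  strategy <- match.arg(strategy, c("combined", "bald", "gan_bald",
                                    "entropy", "confidence", "random"))
  if (maxIterations < 0) stop("maxIterations must be non-negative")
  structure(list(strategy = strategy, acquisition = acquisition,
                 maxIterations = as.integer(maxIterations),
                 labelBudget = labelBudget,
                 initialFraction = initialFraction,
                 initialEpochs = as.integer(initialEpochs),
                 retrainEpochs = as.integer(retrainEpochs),
                 warmStart = warmStart, stopTolerance = stopTolerance,
                 weights = weights, batchSize = as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "loopConfig")
}

evalOnTest <- function(bundle, testX, testY) {
  P <- predictProb(bundle, testX)
  pred <- max.col(P) - 1L
  tp <- sum(pred == 1L & testY == 1L)
  tn <- sum(pred == 0L & testY == 0L)
  fp <- sum(pred == 1L & testY == 0L)
  fn <- sum(pred == 0L & testY == 1L)
  c(accuracy = (tp + tn) / length(testY),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    auc = aucScore(P[, 2L], testY))
}

#' Run the pool-based active-learning loop
#'
#' Splits the train data into an initial stratified labeled pool and an
#' unlabeled pool, trains the CVAE-GAN bundle jointly, then iterates:
#' draw a random candidate batch from D_U, score it under the configured
#' strategy, select the top n, query the oracle, reconstruct the selected
#' samples through the generator (generative arms only), fold originals
#' (and reconstructions) into D_L, and retrain. Stops at
#' \code{maxIterations}, an exhausted label budget or unlabeled pool, or
#' when test accuracy reaches \code{reference - stopTolerance}.
#'
#' @param config a \code{\link{loopConfig}}.
#' @param train ImageSet with ground-truth labels (the oracle's source).
#' @param test ImageSet used for per-iteration evaluation.
#' @param bundle optional pre-built \linkS4class{NetworkBundle}.
#' @param reference optional full-training reference accuracy used by the
#'   convergence stopping rule.
#' @return an \linkS4class{ActiveRun}.
#' @export
runActiveLearning <- function(config, train, test, bundle = NULL,
                              reference = NULL) {
  stopifnot(inherits(config, "loopConfig"))
  seed <- config$seed
  nTrain <- length(train)
  if (nTrain == 0L) stop("train set is empty")

  ## initial stratified labeled pool
  labs <- train@manifest$label
  initIdx <- withSeed(deriveSeed(seed, 1L), {
    idx <- integer()
    for (cl in unique(labs)) {
      clIdx <- which(labs == cl)
      idx <- c(idx, sample(clIdx, max(1L, round(config$initialFraction *
                                                  length(clIdx)))))
    }
    sort(idx)
  })
  labeled <- train[initIdx]
  unlabeled <- train[-initIdx]
  unlabeledHidden <- unlabeled
  unlabeledHidden@manifest$label <- "unknown"
  oracle <- simulatedOracle(train)
  state <- loopState(labeled, unlabeledHidden)
  nOriginals <- length(labeled)

  if (is.null(bundle))
    bundle <- networkBundle(seed = deriveSeed(seed, 2L))
  init <- trainJoint(bundle, state$labeled, state$unlabeled,
                     weights = config$weights, epochs = config$initialEpochs,
                     batchSize = config$batchSize,
                     seed = deriveSeed(seed, 3L))
  bundle <- init$bundle

  testX <- bundleInput(bundle, test)
  testY <- labelIndex(test@manifest$label)

  useRecon <- config$strategy %in% c("combined", "gan_bald")
  history <- list()
  for (it in seq_len(config$maxIterations)) {
    if (length(state$unlabeled) == 0L) break
    nSel <- min(config$acquisition$nSelect, length(state$unlabeled))
    if (is.finite(config$labelBudget) &&
        oracleCount(oracle) + nSel > config$labelBudget) break
    itSeed <- deriveSeed(seed, 1000L + it)
    cand <- samplePool(state, config$acquisition$poolSize,
                       seed = deriveSeed(itSeed, 1L))
    nSel <- min(nSel, length(cand))
    scores <- scorePool(bundle, state$unlabeled[cand], state$labeled,
                        config = config$acquisition,
                        strategy = config$strategy,
                        seed = deriveSeed(itSeed, 2L))
    sel <- rankAndSelect(scores, nSel)
    labsSel <- queryLabel(oracle, sel)
    recon <- NULL
    if (useRecon)
      recon <- reconstructSelected(bundle, state$unlabeled[sel], labsSel,
                                   seed = deriveSeed(itSeed, 3L))
    state <- incorporate(state, sel, labsSel, recon)
    state$iteration <- it
    nOriginals <- nOriginals + nSel
    if (!config$warmStart)
      bundle <- networkBundle(inputSize = bundle@config$inputSize,
                              dZ = bundle@config$dZ,
                              hidden = bundle@config$hidden,
                              dropout = bundle@config$dropout,
                              lr = bundle@config$lr,
                              seed = deriveSeed(itSeed, 4L))
    retr <- trainJoint(bundle, state$labeled, state$unlabeled,
                       weights = config$weights,
                       epochs = if (config$warmStart) config$retrainEpochs
                                else config$initialEpochs,
                       batchSize = config$batchSize,
                       seed = deriveSeed(itSeed, 5L))
    bundle <- retr$bundle
    met <- evalOnTest(bundle, testX, testY)
    history[[length(history) + 1L]] <- data.frame(
      iteration = it, strategy = config$strategy,
      n_labeled = length(state$labeled),
      n_labeled_originals = nOriginals,
      labeled_fraction = nOriginals / nTrain,
      accuracy = met[["accuracy"]], recall = met[["recall"]],
      auc = met[["auc"]],
      selected_ids = paste(sel, collapse = ";"),
      seed = itSeed, stringsAsFactors = FALSE)
    if (!is.null(reference) &&
        met[["accuracy"]] >= reference - config$stopTolerance) break
  }
  hist <- if (length(history)) do.call(rbind, history) else
    data.frame(iteration = integer(), strategy = character(),
               n_labeled = integer(), n_labeled_originals = integer(),
               labeled_fraction = numeric(), accuracy = numeric(),
               recall = numeric(), auc = numeric(),
               selected_ids = character(), seed = integer(),
               stringsAsFactors = FALSE)
  new("ActiveRun", history = hist, bundle = bundle,
      config = unclass(config), queryCount = as.integer(oracleCount(oracle)))
}
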