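#' @import methods
NULL

VALID_LABELS <- c("negative", "positive", "unknown")
VALID_SPLITS <- c("train", "test", "unassigned")
VALID_PROVENANCE <- c("real", "reconstructed", "pseudo", "augmented")

#' ImageSet: an id-indexed collection of RGB patches with a manifest
#'
#' The central data container of the package. Each sample is an RGB patch
#' stored as a numeric array of dimension height x width x 3 with values in
#' [0, 1]; the manifest records, per sample, its unique \code{id}, its
#' \code{label} (\code{"positive"}, \code{"negative"} or \code{"unknown"}),
#' its \code{split} (\code{"train"}, \code{"test"} or \code{"unassigned"})
#' and its \code{provenance} (\code{"real"}, \code{"reconstructed"},
#' \code{"pseudo"} or \code{"augmented"}). Labeled and unlabeled pools in
#' the active-learning loop are both ImageSets.
#'
#' @slot images list of height x width x 3 numeric arrays, values in [0,1].
#' @slot manifest data.frame with columns id, label, split, provenance.
#'
#' @export
setClass("ImageSet", representation(images = "list", manifest = "data.frame"))

setValidity("ImageSet", function(object) {
  msg <- NULL
  man <- object@manifest
  need <- c("id", "label", "split", "provenance")
  if (!all(need %in% colnames(man)))
    return(paste("manifest must have columns", paste(need, collapse = ", ")))
  if (length(object@images) != nrow(man))
    msg <- c(msg, "number of images and manifest rows differ")
  if (anyDuplicated(man$id))
    msg <- c(msg, "sample ids must be unique")
  if (!all(man$label %in% VALID_LABELS))
    msg <- c(msg, "labels must be one of negative/positive/unknown")
  if (!all(man$split %in% VALID_SPLITS))
    msg <- c(msg, "split must be one of train/test/unassigned")
  if (!all(man$provenance %in% VALID_PROVENANCE))
    msg <- c(msg, "provenance must be one of real/reconstructed/pseudo/augmented")
  if (length(object@images)) {
    probe <- object@images[[1L]]
    if (!is.array(probe) || length(dim(probe)) != 3L || dim(probe)[3] != 3L)
      msg <- c(msg, "images must be height x width x 3 arrays")
    else {
      rng <- range(probe)
      if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
        msg <- c(msg, "pixel values must lie in [0, 1]")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an ImageSet
#'
#' @param images list of height x width x 3 arrays with values in [0,1].
#' @param ids character vector of unique sample ids (defaults to s1, s2, ...).
#' @param labels per-sample labels; "unknown" where unlabeled.
#' @param splits per-sample split assignment.
#' @param provenance per-sample provenance.
#' @return an \linkS4class{ImageSet}.
#' @export
ImageSet <- function(images, ids = NULL, labels = "unknown",
                     splits = "unassigned", provenance = "real") {
  n <- length(images)
  if (is.null(ids)) ids <- if (n) paste0("s", seq_len(n)) else character()
  man <- data.frame(
    id = as.character(ids),
    label = rep_len(as.character(labels), n),
    split = rep_len(as.character(splits), n),
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE
  )
  new("ImageSet", images = images, manifest = man)
}

#' NetworkBundle: the four jointly trained networks
#'
#' Holds the encoder E (image to latent mean/log-variance), the
#' class-conditioned generator G (latent + one-hot label to image), the
#' discriminator D (image to real-probability, exposing a penultimate
#' feature vector) and the classifier M (image to class probabilities with
#' dropout, exposing a penultimate feature vector), together with the
#' architecture configuration and Adam optimizer state.
#'
#' @slot encoder,generator,discriminator,classifier lists of dense-layer
#'   parameters and optimizer state.
#' @slot config list: input edge length the networks see, latent dimension
#'   dZ, hidden width, dropout rate, learning rate, number of classes.
#' @slot trained logical; TRUE once \code{trainJoint} has run at least one
#'   epoch.
#' @export
setClass("NetworkBundle", representation(
  encoder = "list", generator = "list", discriminator = "list",
  classifier = "list", config = "list", trained = "logical"
))

#' ActiveRun: the result of an active-learning run
#'
#' @slot history data.frame with one row per executed iteration
#'   (iteration, strategy, labeled pool size, labeled fraction, test
#'   accuracy/recall/AUC, selected ids, seed).
#' @slot bundle the final \linkS4class{NetworkBundle}.
#' @slot config the \code{loopConfig} list used.
#' @slot queryCount total number of oracle queries issued.
#' @export
setClass("ActiveRun", representation(
  history = "data.frame", bundle = "NetworkBundle",
  config = "list", queryCount = "integer"
))
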