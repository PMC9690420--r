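#' @describeIn ImageSet number of samples
#' @param x an ImageSet
#' @export
setMethod("length", "ImageSet", function(x) length(x@images))

#' Sample ids of an ImageSet
#' @param x an ImageSet
#' @return character vector of ids.
#' @export
sampleIds <- function(x) x@manifest$id

#' Manifest accessor
#' @param x an ImageSet
#' @return the manifest data.frame (id, label, split, provenance).
#' @export
sampleManifest <- function(x) x@manifest

#' Per-sample labels
#' @param x an ImageSet
#' @export
sampleLabels <- function(x) stats::setNames(x@manifest$label, x@manifest$id)

#' Per-sample split assignment
#' @param x an ImageSet
#' @export
sampleSplits <- function(x) stats::setNames(x@manifest$split, x@manifest$id)

#' Retrieve one image array by id or position
#' @param x an ImageSet
#' @param i a sample id (character) or index
#' @return a height x width x 3 array.
#' @export
getImage <- function(x, i) {
  if (is.character(i)) {
    i <- match(i, x@manifest$id)
    if (is.na(i)) stop("unknown sample id")
  }
  x@images[[i]]
}

#' @describeIn ImageSet subset by index, logical vector or sample id
#' @param i indices, logicals or ids
#' @param j,drop,... unused
#' @export
setMethod("[", "ImageSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@manifest$id)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  man <- x@manifest[i, , drop = FALSE]
  rownames(man) <- NULL
  new("ImageSet", images = x@images[i], manifest = man)
})

#' Concatenate ImageSets
#'
#' Ids must remain unique across the inputs.
#' @param x an ImageSet
#' @param ... further ImageSets
#' @export
setMethod("c", "ImageSet", function(x, ...) {
  rest <- list(...)
  images <- x@images
  mans <- list(x@manifest)
  for (y in rest) {
    stopifnot(is(y, "ImageSet"))
    images <- c(images, y@images)
    mans <- c(mans, list(y@manifest))
  }
  man <- do.call(rbind, mans)
  rownames(man) <- NULL
  new("ImageSet", images = images, manifest = man)
})

setMethod("show", "ImageSet", function(object) {
  n <- length(object)
  dims <- if (n) paste(dim(object@images[[1L]])[1:2], collapse = "x") else "-"
  cat("ImageSet with", n, "samples (", dims, "pixels )\n")
  if (n) {
    cat("  labels:    ", paste(sprintf("%s=%d", names(table(object@manifest$label)),
                                       table(object@manifest$label)), collapse = " "), "\n")
    cat("  splits:    ", paste(sprintf("%s=%d", names(table(object@manifest$split)),
                                       table(object@manifest$split)), collapse = " "), "\n")
    cat("  provenance:", paste(sprintf("%s=%d", names(table(object@manifest$provenance)),
                                       table(object@manifest$provenance)), collapse = " "), "\n")
  }
})

setMethod("show", "NetworkBundle", function(object) {
  cfg <- object@config
  cat("NetworkBundle (conditional VAE-GAN + classifier)\n")
  cat("  net input:", cfg$inputSize, "x", cfg$inputSize, "x 3 ; dZ =", cfg$dZ,
      "; hidden =", cfg$hidden, "; dropout =", cfg$dropout, "\n")
  cat("  trained:", object@trained, "\n")
})

setMethod("show", "ActiveRun", function(object) {
  cat("ActiveRun:", nrow(object@history), "iterations, strategy",
      object@config$strategy, "\n")
  cat("  oracle queries:", object@queryCount, "\n")
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  final: |D_L| = %d, accuracy = %.4f, recall = %.4f, AUC = %.4f\n",
                last$n_labeled, last$accuracy, last$recall, last$auc))
  }
})

#' Run history accessor
#' @param run an \linkS4class{ActiveRun}
#' @return data.frame of per-iteration records.
#' @export
runHistory <- function(run) run@history

#' Total oracle queries issued during a run
#' @param run an \linkS4class{ActiveRun}
#' @export
oracleQueries <- function(run) run@queryCount
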