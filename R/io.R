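## Disk formats: PNG images + CSV manifest for datasets, CSV for scores,
## JSONL for run histories.

labelTo01 <- function(lab) ifelse(lab == "positive", "1",
                                  ifelse(lab == "negative", "0", ""))
labelFrom01 <- function(v) ifelse(v %in% "1", "positive",
                                  ifelse(v %in% "0", "negative", "unknown"))

#' Write an ImageSet to disk
#'
#' Images are written as PNG under \code{dir/images/}, and the manifest as
#' \code{dir/manifest.csv} with header \code{id,path,label,split}; labels
#' are serialized as 0/1 (1 = positive, blank = unknown).
#'
#' @param x an ImageSet.
#' @param dir output directory.
#' @param force overwrite an existing manifest (default FALSE: error).
#' @return the manifest path, invisibly.
#' @export
writeImageSet <- function(x, dir, force = FALSE) {
  manPath <- file.path(dir, "manifest.csv")
  if (file.exists(manPath) && !force)
    stop("manifest already exists at ", manPath, "; use force = TRUE")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  ids <- sampleIds(x)
  paths <- file.path("images", paste0(ids, ".png"))
  for (i in seq_along(ids))
    png::writePNG(x@images[[i]], file.path(dir, paths[i]))
  man <- data.frame(id = ids, path = paths,
                    label = labelTo01(x@manifest$label),
                    split = x@manifest$split, stringsAsFactors = FALSE)
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  invisible(manPath)
}

#' Read an ImageSet written by \code{\link{writeImageSet}}
#'
#' @param dir dataset directory containing manifest.csv.
#' @return an ImageSet.
#' @export
readImageSet <- function(dir) {
  manPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manPath)) stop("no manifest.csv under ", dir)
  man <- utils::read.csv(manPath, colClasses = "character")
  imgs <- lapply(man$path, function(p) {
    a <- png::readPNG(file.path(dir, p))
    if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
  ImageSet(imgs, ids = man$id, labels = labelFrom01(man$label),
           splits = ifelse(man$split %in% VALID_SPLITS, man$split,
                           "unassigned"))
}

#' Export per-iteration acquisition scores as CSV
#'
#' Columns: iteration, sample_id, uncertainty, diversity, unc_scaled,
#' div_scaled, combined, selected.
#'
#' @param scores data.frame from \code{\link{scorePool}}.
#' @param path output CSV path.
#' @param iteration iteration index to record.
#' @param selectedIds ids that were selected this iteration.
#' @param append append to an existing file (default FALSE).
#' @export
writeScores <- function(scores, path, iteration = 1L,
                        selectedIds = character(), append = FALSE) {
  out <- cbind(iteration = iteration, scores,
               selected = as.integer(scores$sample_id %in% selectedIds))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
  invisible(path)
}

#' Write a run history as JSON lines
#'
#' One JSON object per executed iteration, as produced by
#' \code{runHistory}.
#'
#' @param history data.frame of per-iteration records.
#' @param path output path.
#' @export
writeHistoryJsonl <- function(history, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writeHistoryJsonl requires the jsonlite package")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(history)))
    writeLines(jsonlite::toJSON(as.list(history[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

#' Read a JSONL run history
#' @param path path written by \code{\link{writeHistoryJsonl}}.
#' @return data.frame of per-iteration records.
#' @export
readHistoryJsonl <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("readHistoryJsonl requires the jsonlite package")
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}
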