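# Volume and table I/O. Grey volumes and label volumes travel as multi-page
# TIFF stacks (one page per z slice, 16-bit); segment tables and morphometry
# tables as CSV.

#' Read a grey-value volume from a multi-page TIFF stack
#'
#' Pages are stacked along the third (z = cutting) axis. Intensities are
#' min-max normalized to [0, 1]; a constant stack maps to all-zero by
#' convention (with a warning), so noise-free synthetic backgrounds pass
#' through.
#'
#' @param path TIFF file with one page per slice.
#' @param voxelSize numeric(3) voxel size (hy, hx, hz) in nm.
#' @return an \linkS4class{SBEMVolume}.
#' @export
readVolume <- function(path, voxelSize) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  if (any(voxelSize <= 0)) stop("voxel size must be positive")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1L))))
    stop("expected single-channel grayscale pages")
  arr <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  rng <- range(arr)
  if (rng[2L] > rng[1L]) {
    arr <- (arr - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    warning("constant-intensity volume; normalized to 0")
    arr[] <- 0
  }
  SBEMVolume(arr, voxelSize)
}

#' Write a grey-value volume as a 16-bit multi-page TIFF
#'
#' @param vol an \linkS4class{SBEMVolume}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeVolume <- function(vol, path) {
  arr <- volData(vol)
  pages <- lapply(seq_len(dim(arr)[3L]), function(k) arr[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a segmentation (labels + segment table)
#'
#' Labels are stored as a 16-bit multi-page TIFF (value = label id), the
#' segment table as CSV with one row per segment. The pair is checked for
#' consistency (class validity) before writing.
#'
#' @param seg an \linkS4class{AxonSegmentation}.
#' @param path label TIFF path.
#' @param tablePath segment-table CSV path.
#' @return invisibly, \code{path}.
#' @export
writeLabels <- function(seg, path, tablePath) {
  validObject(seg)
  lab <- labelData(seg)
  if (max(lab) > 65535L) stop("label ids exceed 16-bit storage")
  pages <- lapply(seq_len(dim(lab)[3L]), function(k) lab[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  utils::write.csv(segmentTable(seg), tablePath, row.names = FALSE)
  invisible(path)
}

#' Read a segmentation written by \code{writeLabels}
#'
#' @param path label TIFF path.
#' @param tablePath segment-table CSV path (optional; rebuilt if missing).
#' @param voxelSize numeric(3) in nm.
#' @return an \linkS4class{AxonSegmentation}.
#' @export
readLabels <- function(path, tablePath = NULL, voxelSize) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(as.integer(round(unlist(pages) * 65535)),
               dim = c(dim(pages[[1L]]), length(pages)))
  tab <- NULL
  if (!is.null(tablePath)) {
    tab <- utils::read.csv(tablePath, stringsAsFactors = FALSE)
    tab$id <- as.integer(tab$id)
    tab$voxel_count <- as.integer(tab$voxel_count)
    tab$parent_axon_id <- as.integer(tab$parent_axon_id)
    tab$review_flag <- as.logical(tab$review_flag)
  }
  AxonSegmentation(arr, voxelSize, tab)
}
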