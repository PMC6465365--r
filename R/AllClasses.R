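#' @import methods
NULL

.SEGMENT_CLASSES <- c("MYELIN", "MYELINATED_AXON", "UNMYELINATED_AXON",
                      "MITOCHONDRION", "VACUOLE", "CELL", "UNCLASSIFIED")

#' SBEMVolume: a normalized 3D electron-microscopy intensity volume
#'
#' Container for a serial block-face EM grey-value volume. Intensities are
#' dimensionless in [0, 1]; the array is indexed (y, x, z) with z the cutting
#' (sectioning) axis. The voxel size is anisotropic: in-plane isotropic
#' (hy == hx) and at least as coarse along z, as acquired.
#'
#' @slot data numeric 3D array of intensities in [0, 1].
#' @slot voxelSize numeric(3), voxel size (hy, hx, hz) in nm.
#' @export
setClass("SBEMVolume",
  representation(data = "array", voxelSize = "numeric"))

setValidity("SBEMVolume", function(object) {
  d <- object@data
  v <- object@voxelSize
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (length(v) != 3L || any(!is.finite(v)) || any(v <= 0))
    return("voxelSize must be three positive values (nm)")
  if (abs(v[1L] - v[2L]) > 1e-9)
    return("in-plane voxel size must be isotropic (hy == hx)")
  if (v[3L] < v[1L] - 1e-9)
    return("z voxel size must not be finer than in-plane (vz >= vx)")
  if (any(!is.finite(d))) return("intensities must be finite")
  rng <- range(d)
  if (rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
    return("intensities must lie in [0, 1]")
  TRUE
})

#' Construct an SBEMVolume
#'
#' @param data numeric 3D array, intensities in [0, 1], indexed (y, x, z).
#' @param voxelSize numeric(3) voxel size (hy, hx, hz) in nm.
#' @return an \linkS4class{SBEMVolume}.
#' @export
SBEMVolume <- function(data, voxelSize) {
  new("SBEMVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' AxonSegmentation: labelled partition of a volume with per-segment classes
#'
#' Integer labels (0 = unassigned) over the same grid as the parent volume,
#' paired with a segment table holding one row per label: its class (myelin,
#' myelinated/unmyelinated axon, mitochondrion, vacuole, cell, or
#' unclassified), voxel count, optional parent axon for organelles, and a
#' review flag marking decisions the pipeline wants proof-read.
#'
#' @slot labels integer 3D array.
#' @slot voxelSize numeric(3) in nm.
#' @slot segments data.frame with columns id, klass, voxel_count,
#'   parent_axon_id, review_flag.
#' @export
setClass("AxonSegmentation",
  representation(labels = "array", voxelSize = "numeric",
                 segments = "data.frame"))

setValidity("AxonSegmentation", function(object) {
  lab <- object@labels
  tab <- object@segments
  if (length(dim(lab)) != 3L) return("labels must be a 3D array")
  need <- c("id", "klass", "voxel_count", "parent_axon_id", "review_flag")
  if (!all(need %in% names(tab)))
    return(paste("segment table must have columns:",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(tab$id)) return("segment ids must be unique")
  if (!all(tab$klass %in% .SEGMENT_CLASSES))
    return("unknown segment class")
  counts <- tabulate(lab[lab > 0L], nbins = max(c(tab$id, 1L)))
  ids <- sort(unique(lab[lab > 0L]))
  if (!all(ids %in% tab$id))
    return("every nonzero label needs a segment-table row")
  for (r in seq_len(nrow(tab))) {
    if (counts[tab$id[r]] != tab$voxel_count[r])
      return(sprintf("voxel_count mismatch for segment %d (%d != %d)",
                     tab$id[r], tab$voxel_count[r], counts[tab$id[r]]))
  }
  pa <- tab$parent_axon_id
  ok <- tab$id[tab$klass %in% c("MYELINATED_AXON", "UNMYELINATED_AXON",
                                "UNCLASSIFIED")]
  if (any(!is.na(pa) & !(pa %in% ok)))
    return("parent_axon_id must reference an axon (or yet-unclassified) segment")
  TRUE
})

#' Construct an AxonSegmentation
#'
#' @param labels integer 3D array (0 = unassigned).
#' @param voxelSize numeric(3) in nm.
#' @param segments segment table; if NULL, one UNCLASSIFIED row per label is
#'   generated.
#' @return an \linkS4class{AxonSegmentation}.
#' @export
AxonSegmentation <- function(labels, voxelSize, segments = NULL) {
  storage.mode(labels) <- "integer"
  if (is.null(segments)) {
    ids <- sort(unique(labels[labels > 0L]))
    counts <- if (length(ids)) tabulate(labels[labels > 0L], nbins = max(ids))
              else integer(0)
    segments <- data.frame(id = as.integer(ids),
                           klass = rep("UNCLASSIFIED", length(ids)),
                           voxel_count = as.integer(counts[ids]),
                           parent_axon_id = rep(NA_integer_, length(ids)),
                           review_flag = rep(FALSE, length(ids)),
                           stringsAsFactors = FALSE)
  }
  new("AxonSegmentation", labels = labels, voxelSize = as.numeric(voxelSize),
      segments = segments)
}

#' Skeleton: sub-voxel axonal centreline
#'
#' Ordered 3D polyline through the interior of one axon, sampled at
#' (nominally) 25 nm arc-length steps, with the deepest interior point and
#' the two endpoints recorded, and optionally trimmed by a fixed arc length
#' at both ends (endpoints of the untrimmed path lie on the axon surface).
#'
#' @slot points numeric matrix (n x 3) of (y, x, z) positions in nm.
#' @slot arcLength numeric(n), cumulative arc length in nm from the first
#'   point.
#' @slot keyPoints list with elements xstar, e1, e2 (positions in nm).
#' @slot trimmed logical, whether end-trimming has been applied.
#' @slot axonId integer id of the axon the skeleton belongs to.
#' @export
setClass("Skeleton",
  representation(points = "matrix", arcLength = "numeric",
                 keyPoints = "list", trimmed = "logical", axonId = "integer"))

setValidity("Skeleton", function(object) {
  p <- object@points
  if (ncol(p) != 3L) return("points must be an n x 3 matrix")
  if (nrow(p) != length(object@arcLength))
    return("arcLength must match the number of points")
  if (nrow(p) > 1L) {
    steps <- diff(object@arcLength)
    if (any(steps < -1e-9)) return("arc length must be nondecreasing")
  }
  TRUE
})

## ---- generics and accessors -------------------------------------------------

#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' Voxel size accessor
#' @param x an SBEMVolume or AxonSegmentation.
#' @return numeric(3) voxel size (hy, hx, hz) in nm.
#' @export
setMethod("voxelSize", "SBEMVolume", function(x) x@voxelSize)
#' @export
setMethod("voxelSize", "AxonSegmentation", function(x) x@voxelSize)

#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' Intensity array accessor
#' @param x an SBEMVolume.
#' @return the numeric 3D intensity array, indexed (y, x, z).
#' @export
setMethod("volData", "SBEMVolume", function(x) x@data)

#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' Label array accessor
#' @param x an AxonSegmentation.
#' @return integer 3D label array (0 = unassigned).
#' @export
setMethod("labelData", "AxonSegmentation", function(x) x@labels)

#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' Segment table accessor
#' @param x an AxonSegmentation.
#' @return data.frame with one row per segment.
#' @export
setMethod("segmentTable", "AxonSegmentation", function(x) x@segments)

#' @export
setGeneric("skelPoints", function(x) standardGeneric("skelPoints"))
#' Skeleton point accessor
#' @param x a Skeleton.
#' @return numeric matrix (n x 3) of (y, x, z) positions in nm.
#' @export
setMethod("skelPoints", "Skeleton", function(x) x@points)

#' @export
setGeneric("skelLength", function(x) standardGeneric("skelLength"))
#' Skeleton length
#' @param x a Skeleton.
#' @return total arc length in micrometres.
#' @export
setMethod("skelLength", "Skeleton",
          function(x) {
            if (nrow(x@points) < 2L) return(0)
            (max(x@arcLength) - min(x@arcLength)) / 1000
          })

setMethod("dim", "SBEMVolume", function(x) dim(x@data))
setMethod("dim", "AxonSegmentation", function(x) dim(x@labels))

setMethod("show", "SBEMVolume", function(object) {
  d <- dim(object@data)
  v <- object@voxelSize
  cat(sprintf("SBEMVolume: %d x %d x %d voxels (%.2f x %.2f x %.2f um)\n",
              d[1], d[2], d[3], d[1] * v[1] / 1e3, d[2] * v[2] / 1e3,
              d[3] * v[3] / 1e3))
  cat(sprintf("  voxel size %.1f x %.1f x %.1f nm; intensity range [%.3f, %.3f]\n",
              v[1], v[2], v[3], min(object@data), max(object@data)))
})

setMethod("show", "AxonSegmentation", function(object) {
  tab <- object@segments
  d <- dim(object@labels)
  cat(sprintf("AxonSegmentation: %d x %d x %d voxels, %d segments\n",
              d[1], d[2], d[3], nrow(tab)))
  if (nrow(tab)) {
    cls <- table(factor(tab$klass, levels = .SEGMENT_CLASSES))
    cls <- cls[cls > 0]
    cat("  ", paste(sprintf("%s: %d", names(cls), cls), collapse = ", "), "\n")
  }
  unl <- sum(object@labels == 0L)
  cat(sprintf("  unassigned voxels: %d (%.1f%%)\n", unl,
              100 * unl / prod(d)))
})

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton (axon %d): %d points, %.2f um%s\n",
              object@axonId, nrow(object@points), skelLength(object),
              if (isTRUE(object@trimmed)) ", trimmed" else ""))
})
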