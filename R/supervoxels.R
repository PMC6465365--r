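# SLIC supervoxels and supervoxel-based segmentation refinement.

#' Compute SLIC supervoxels
#'
#' Localized k-means with distance D = d_int + (c / rho) * d_sp. d_int is
#' the absolute intensity difference on a 0-255 grey scale; d_sp the
#' Euclidean distance in scaled voxel coordinates, where the per-axis scale
#' defaults to (1, 1, vz/vx) so that one z step (a 50 nm section) counts its
#' true physical length relative to the fine in-plane grid and supervoxels
#' come out compact in physical space. Centres start on a regular grid of
#' step rho (scaled units), iterate to convergence, and connectivity is
#' enforced (orphan fragments merge into an adjacent supervoxel).
#'
#' @param vol an \linkS4class{SBEMVolume}.
#' @param compactness c (default 23).
#' @param step grid step rho in (in-plane) voxels (default 11, must be >= 2).
#' @param spacing per-axis scale of the spatial distance; default
#'   c(1, 1, vz/vx).
#' @param maxIter,tol iteration cap and centre-shift tolerance (voxels).
#' @return list of class \code{SupervoxelPartition}: integer array
#'   \code{labels} (1..Q, full partition), \code{Q}, \code{params}.
#' @export
computeSupervoxels <- function(vol, compactness = 23, step = 11,
                               spacing = NULL, maxIter = 10L, tol = 1e-3) {
  if (step < 2) stop("grid step rho must be at least 2")
  if (compactness <= 0) stop("compactness must be positive")
  z <- volData(vol)
  vs <- voxelSize(vol)
  if (is.null(spacing)) spacing <- c(1, 1, vs[3L] / vs[1L])
  lab <- slic_cpp(z, dim(z), compactness, step, as.numeric(spacing),
                  as.integer(maxIter), tol)
  structure(list(labels = array(as.integer(lab), dim(z)),
                 Q = attr(lab, "Q"),
                 params = list(compactness = compactness, step = step,
                               spacing = spacing)),
            class = "SupervoxelPartition")
}

#' Refine a segmentation with supervoxels
#'
#' Each large segment (>= \code{minLarge} voxels), visited in ascending id
#' (the serial creation order), claims every supervoxel that it overlaps by
#' at least 0.8 of the supervoxel's volume and that was not already claimed
#' by an earlier segment; claimed supervoxels are attached wholly, which is
#' how edge-barrier voxels and small fragments get absorbed into the larger
#' segments. A tie at exactly 0.8 counts as claimed. Voxels the growing
#' stage assigned to a large segment are never taken away from it by the
#' refinement (boundary supervoxels of thin structures always mix in
#' barrier voxels, so a strict supervoxel-union replacement would strip
#' sheath boundaries). Segments that remain smaller than \code{minLarge}
#' are dropped, their voxels unlabelled unless claimed.
#'
#' @param seg an \linkS4class{AxonSegmentation} (serial BVG labels).
#' @param sv a \code{SupervoxelPartition} on the same grid.
#' @param minLarge small-volume threshold (default 5e3 voxels).
#' @param overlap claiming threshold (default 0.8).
#' @return a refined \linkS4class{AxonSegmentation} (ids preserved).
#' @export
refineLabels <- function(seg, sv, minLarge = 5e3, overlap = 0.8) {
  labels <- labelData(seg)
  if (!identical(dim(labels), dim(sv$labels)))
    stop("segmentation and supervoxels have different shapes")
  svl <- sv$labels
  Q <- sv$Q
  svSize <- tabulate(svl, nbins = Q)
  tab <- segmentTable(seg)
  ord <- order(tab$id)
  ids <- tab$id[ord]
  sizes <- tab$voxel_count[ord]
  large <- ids[sizes >= minLarge]

  svOwner <- integer(Q)              # 0 = unclaimed
  for (id in large) {
    cnt <- tabulate(svl[labels == id], nbins = Q)
    frac <- cnt / svSize
    q <- which(frac >= overlap & svOwner == 0L)
    svOwner[q] <- id
  }
  newLabels <- labels
  newLabels[!(labels %in% large)] <- 0L      # small volumes dissolve
  owned <- svOwner[svl]
  pos <- owned != 0L
  newLabels[pos] <- owned[pos]               # claimed supervoxels attach
  AxonSegmentation(newLabels, voxelSize(seg))
}
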