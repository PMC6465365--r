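# Subcellular and cellular annotation: mitochondria as closed cavities of
# axon segments, the vacuole intensity/size rule, myelinated vs unmyelinated
# classification by the myelin content of the enclosing supervoxel shell,
# cell labelling of voxels left over by the volume cap, and the myelin
# redefinition MY = V1 minus mitochondria.

#' Morphological closing with a physical radius
#'
#' Closing by a Euclidean ball of radius \code{radiusNm}: dilation then
#' erosion, both via the anisotropy-aware distance transform (the radius is
#' physical, which matters with 50 nm sections against ~15 nm pixels).
#' Cavities with inradius below the closing radius are filled.
#'
#' @param mask logical 3D array.
#' @param voxelSize numeric(3) nm.
#' @param radiusNm closing radius in nm.
#' @return logical array, the closed mask.
#' @export
closeMask <- function(mask, voxelSize, radiusNm) {
  # pad with background by the closing radius so the morphology treats the
  # outside of the array as complement (otherwise regions touching the
  # volume border grow fake cavities there)
  d <- dim(mask)
  pad <- ceiling(radiusNm / voxelSize) + 1
  dp <- d + 2 * pad
  big <- array(FALSE, dp)
  iy <- pad[1L] + seq_len(d[1L]); ix <- pad[2L] + seq_len(d[2L])
  iz <- pad[3L] + seq_len(d[3L])
  big[iy, ix, iz] <- mask
  dil <- distanceTransform(big, voxelSize) <= radiusNm
  closed <- distanceTransform(!dil, voxelSize) >= radiusNm
  closed[iy, ix, iz]
}

#' Detect mitochondria as closed cavities of an axon segment
#'
#' The surface of the segment is propagated outward for the closing radius
#' (default 1 um) and back; cavities smaller than the radius close and the
#' difference to the original segment yields candidates, which are then
#' snapped to supervoxels (claiming rule: supervoxels covered at least 0.8
#' by the candidate set). Every candidate carries a review flag: a cavity
#' can also be a myelin fold, and the final call is left to proof-reading.
#'
#' @param axonMask logical array, one refined axon segment.
#' @param sv a \code{SupervoxelPartition} (NULL to skip snapping).
#' @param voxelSize numeric(3) nm.
#' @param closingRadius closing radius in nm (default 1000).
#' @param minParent minimum segment size for cavity detection (default 1e4
#'   voxels); smaller segments return no candidates.
#' @return list of integer vectors (linear voxel indices), one per candidate
#'   (26-connected component), with attribute \code{review_flag = TRUE}.
#' @export
detectMitochondria <- function(axonMask, sv = NULL, voxelSize,
                               closingRadius = 1000, minParent = 1e4) {
  if (sum(axonMask) <= minParent) return(structure(list(), review_flag = TRUE))
  # work on the bounding box (the padded closing is quadratic in volume)
  w <- which(axonMask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2L, min) - 2L, 1L)
  hi <- pmin(apply(w, 2L, max) + 2L, dim(axonMask))
  sub <- axonMask[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L], drop = FALSE]
  closedSub <- closeMask(sub, voxelSize, closingRadius)
  closed <- array(FALSE, dim(axonMask))
  closed[lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L]] <- closedSub
  cand <- closed & !axonMask
  if (!is.null(sv) && any(cand)) {
    Q <- sv$Q
    svSize <- tabulate(sv$labels, nbins = Q)
    cnt <- tabulate(sv$labels[cand], nbins = Q)
    q <- which(cnt / svSize >= 0.8)
    cand <- array(sv$labels %in% q, dim(axonMask)) & !axonMask
  }
  if (!any(cand)) return(structure(list(), review_flag = TRUE))
  lab <- connectedComponents(cand, 26L)
  comps <- split(which(lab > 0L), lab[lab > 0L])
  structure(unname(comps), review_flag = TRUE)
}

#' Classify vacuoles by size and brightness
#'
#' A segment is a vacuole iff it is small (voxel_count below
#' \code{maxSize}) and very bright (mean intensity at least \code{minMean});
#' vacuoles appear brighter than every other ultrastructure.
#'
#' @param seg an \linkS4class{AxonSegmentation}.
#' @param vol the matching \linkS4class{SBEMVolume}.
#' @param maxSize,minMean rule constants (defaults 2e4 voxels, 0.85).
#' @return the segmentation with vacuole rows reclassified.
#' @export
classifyVacuoles <- function(seg, vol, maxSize = 2e4, minMean = 0.85) {
  tab <- segmentTable(seg)
  labels <- labelData(seg)
  z <- volData(vol)
  means <- rep(NA_real_, nrow(tab))
  pos <- labels > 0L
  sums <- rowsum(z[pos], labels[pos])
  meanById <- sums[, 1L] / tabulate(labels[pos], nbins = max(tab$id))[as.integer(rownames(sums))]
  names(meanById) <- rownames(sums)
  for (r in seq_len(nrow(tab))) {
    if (!tab$klass[r] %in% c("UNCLASSIFIED")) next
    mu <- meanById[[as.character(tab$id[r])]]
    if (!is.null(mu) && !is.na(mu) &&
        tab$voxel_count[r] < maxSize && mu >= minMean)
      tab$klass[r] <- "VACUOLE"
  }
  initialize(seg, segments = tab)
}

#' Classify axons as myelinated or unmyelinated
#'
#' For each axon candidate the enclosing shell is collected: the supervoxels
#' sharing a face (6-connectivity) with the segment whose content is not
#' majority axon (segments keep their grown boundary voxels, so a strict
#' "not part of the axon" reading would leave no shell at all). The myelin
#' fraction of the shell's non-axon voxels decides the class: at least
#' \code{threshold} means myelinated. Borderline fractions (within
#' \code{band} of the threshold) and axons with an empty shell are flagged
#' for review; an empty-shell axon defaults to unmyelinated.
#'
#' @param seg an \linkS4class{AxonSegmentation} (vacuoles already labelled).
#' @param sv a \code{SupervoxelPartition}.
#' @param myelin logical array, the (redefined) myelin mask MY.
#' @param threshold myelin-fraction threshold (default 0.7, inclusive).
#' @param band review-flag band around the threshold (default 0.05).
#' @return the segmentation with axon rows classified.
#' @export
classifyAxons <- function(seg, sv, myelin, threshold = 0.7, band = 0.05) {
  tab <- segmentTable(seg)
  labels <- labelData(seg)
  svl <- sv$labels
  Q <- sv$Q
  svMy <- tabulate(svl[myelin], nbins = Q)
  svSize <- tabulate(svl, nbins = Q)
  for (r in seq_len(nrow(tab))) {
    if (tab$klass[r] != "UNCLASSIFIED") next
    id <- tab$id[r]
    region <- labels == id
    svAx <- tabulate(svl[region], nbins = Q)
    axSv <- which(svAx / svSize >= 0.5)          # the axon's own supervoxels
    if (length(axSv) == 0L) axSv <- which(svAx > 0L)
    core <- array(svl %in% axSv, dim(labels))
    shell <- .dilate6(core) & !core
    lam <- setdiff(unique(svl[shell]), axSv)
    denom <- sum(svSize[lam]) - sum(svAx[lam])
    if (length(lam) == 0L || denom == 0L) {
      tab$klass[r] <- "UNMYELINATED_AXON"
      tab$review_flag[r] <- TRUE
      next
    }
    frac <- sum(svMy[lam]) / denom
    tab$klass[r] <- if (frac >= threshold) "MYELINATED_AXON" else "UNMYELINATED_AXON"
    if (abs(frac - threshold) <= band) tab$review_flag[r] <- TRUE
  }
  initialize(seg, segments = tab)
}

# 6-neighbourhood binary dilation
.dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  n1 <- d[1L]; n2 <- d[2L]; n3 <- d[3L]
  out[-1, , ] <- out[-1, , ] | mask[-n1, , ]
  out[-n1, , ] <- out[-n1, , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -n2, ]
  out[, -n2, ] <- out[, -n2, ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -n3]
  out[, , -n3] <- out[, , -n3] | mask[, , -1]
  out
}

#' Label cell bodies and processes
#'
#' Voxels left unassigned after refinement (volumes that exceeded the growth
#' cap) are grouped by 26-connected component analysis; each component
#' becomes a CELL segment.
#'
#' @param unlabelled logical array of unassigned voxels.
#' @param minSize drop components smaller than this (default 0).
#' @return integer array of cell labels (0 = none) and the component count
#'   as attribute \code{n}.
#' @export
labelCells <- function(unlabelled, minSize = 0L) {
  lab <- connectedComponents(unlabelled, 26L)
  if (minSize > 0L && max(lab) > 0L) {
    sz <- tabulate(lab[lab > 0L])
    drop <- which(sz < minSize)
    lab[lab %in% drop] <- 0L
    keep <- sort(unique(lab[lab > 0L]))
    lab[] <- match(lab, keep, nomatch = 0L)
  }
  structure(lab, n = max(lab))
}

#' Redefine myelin by removing mitochondria
#'
#' @param V1 logical array, the dark structure (myelin + mitochondria).
#' @param mitochondria list of integer voxel-index vectors.
#' @return logical array MY = V1 minus all mitochondria.
#' @export
redefineMyelin <- function(V1, mitochondria) {
  MY <- V1
  for (m in mitochondria) MY[m] <- FALSE
  MY
}
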