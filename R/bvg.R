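# Bounded volume growing (BVG): seeded region growing constrained by dilated
# edge barriers and a volume cap. A region grows in batches: every candidate
# neighbour whose intensity is within delta_T of the running region mean is
# appended, the mean is recomputed, and growth repeats until nothing
# qualifies; a region that reaches the cap theta is discarded and its voxels
# freed. Growing is serial: later seeds cannot enter earlier regions.

#' Grow one region by bounded volume growing
#'
#' @param vol an \linkS4class{SBEMVolume}.
#' @param seed seed voxel: linear index or (y, x, z) triple (1-based).
#' @param forbidden logical array of barrier voxels (edges + previously
#'   claimed regions); the seed must not be forbidden.
#' @param deltaT intensity similarity threshold (default 0.1).
#' @param theta volume cap in voxels (Inf = uncapped).
#' @param connectivity 6 or 26.
#' @return integer vector of 1-based linear voxel indices of the region, with
#'   attribute \code{discarded}: TRUE means the region hit the cap and its
#'   voxels must be treated as free.
#' @export
bvgGrow <- function(vol, seed, forbidden = NULL, deltaT = 0.1, theta = Inf,
                    connectivity = 6L) {
  z <- volData(vol)
  d <- dim(z)
  if (length(seed) == 3L) seed <- .ijkToInd(seed, d)
  if (is.null(forbidden)) forbidden <- array(FALSE, d)
  stopifnot(deltaT > 0, deltaT < 1, connectivity %in% c(6L, 26L))
  res <- bvg_grow_cpp(z, d, as.integer(seed - 1L), as.logical(forbidden),
                      deltaT, theta, as.integer(connectivity))
  structure(as.integer(res) + 1L, discarded = isTRUE(attr(res, "discarded")))
}

#' Segment the connected dark structure (myelin + mitochondria)
#'
#' One BVG run with 26-connectivity and no volume cap from a single random
#' low-intensity seed: myelin is a connected structure across consecutive
#' sections, so one seed suffices to cover it (mitochondria adjoining it are
#' swept up too and separated later).
#'
#' @param vol an \linkS4class{SBEMVolume} (denoised).
#' @param edges an \code{EdgeMask} from \code{\link{detectEdges}}.
#' @param maxSeedIntensity seed must satisfy z(seed) <= this (default 0.4).
#' @param deltaT similarity threshold.
#' @param seed RNG seed for drawing the starting voxel.
#' @return logical array: the dark structure V1.
#' @export
segmentMyelin <- function(vol, edges, maxSeedIntensity = 0.4, deltaT = 0.1,
                          seed = 1L) {
  z <- volData(vol)
  cand <- which(z <= maxSeedIntensity & !edges$dilated)
  if (length(cand) == 0L)
    stop("no qualifying myelin seed (no voxel below the intensity bound)")
  s <- withSeed(seed, sample(cand, 1L))
  idx <- bvgGrow(vol, s, forbidden = edges$dilated, deltaT = deltaT,
                 theta = Inf, connectivity = 26L)
  out <- array(FALSE, dim(z))
  out[as.integer(idx)] <- TRUE
  out
}

#' Boundary mask for seeding
#'
#' @param edges an \code{EdgeMask}.
#' @param myelin logical array (the V1 segment).
#' @return logical array B = dilated edges OR myelin.
#' @export
boundaryMask <- function(edges, myelin) {
  edges$dilated | myelin
}

#' Extract growth seeds from the boundary mask
#'
#' For every z slice the 2D Euclidean distance transform to the boundary set
#' is computed and its regional maxima become seeds: the deepest interior
#' points of the structures enclosed by myelin and edges. A plateau of
#' maxima contributes one seed (the plateau voxel nearest its centroid).
#' Slices entirely inside (or entirely free of) the boundary contribute no
#' seeds. Seed order is slice-major, then scan order within the slice.
#'
#' @param B logical array from \code{\link{boundaryMask}}.
#' @param voxelSize numeric(3) in nm.
#' @return data.frame with columns y, x, z (1-based voxel indices) and slice.
#' @export
extractSeeds <- function(B, voxelSize) {
  d <- dim(B)
  out <- vector("list", d[3L])
  for (k in seq_len(d[3L])) {
    sl <- B[, , k]
    if (all(sl) || !any(sl)) next
    dt <- distanceTransform(array(sl, c(d[1L], d[2L], 1L)),
                            c(voxelSize[1L], voxelSize[2L], 1))[, , 1L]
    mx <- .regionalMaxima2d(dt)
    if (nrow(mx) == 0L) next
    out[[k]] <- data.frame(y = mx[, 1L], x = mx[, 2L], z = k, slice = k)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res))
    res <- data.frame(y = integer(0), x = integer(0), z = integer(0),
                      slice = integer(0))
  res
}

# regional maxima of a 2D map with plateau handling: one representative voxel
# (nearest the plateau centroid) per connected plateau of local maxima
.regionalMaxima2d <- function(dt) {
  ny <- nrow(dt); nx <- ncol(dt)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- dt
  mx <- matrix(-Inf, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    mx <- pmax(mx, pad[2:(ny + 1L) + dy, 2:(nx + 1L) + dx])
  }
  isMax <- dt >= mx & dt > 0
  if (!any(isMax)) return(matrix(integer(0), 0L, 2L))
  lab <- connectedComponents(array(isMax, c(ny, nx, 1L)), 26L)[, , 1L]
  ids <- seq_len(max(lab))
  res <- matrix(0L, length(ids), 2L)
  for (id in ids) {
    w <- which(lab == id)
    yy <- (w - 1L) %% ny + 1L
    xx <- (w - 1L) %/% ny + 1L
    cy <- mean(yy); cx <- mean(xx)
    pick <- which.min((yy - cy)^2 + (xx - cx)^2)
    res[id, ] <- c(yy[pick], xx[pick])
  }
  # scan order within the slice (column-major linear index)
  res[order(res[, 2L], res[, 1L]), , drop = FALSE]
}

#' Serial BVG segmentation of the intra-cellular volumes
#'
#' Seeds are processed in order; a seed falling in an already-claimed region
#' is skipped (the serial nature of the growing forbids repeated
#' segmentation), each accepted run becomes a new label, and runs that reach
#' the volume cap are discarded with their voxels freed. Boundary-mask
#' voxels stay unlabelled at this stage.
#'
#' @param vol an \linkS4class{SBEMVolume}.
#' @param B logical boundary mask (stays unlabelled).
#' @param seeds data.frame from \code{\link{extractSeeds}}.
#' @param deltaT similarity threshold (default 0.1).
#' @param theta volume cap in voxels (default 1e6).
#' @param connectivity neighbourhood for growing (default 6).
#' @param firstLabel id of the first new segment (default 1).
#' @return an \linkS4class{AxonSegmentation} with UNCLASSIFIED segments.
#' @export
segmentVolume <- function(vol, B, seeds, deltaT = 0.1, theta = 1e6,
                          connectivity = 6L, firstLabel = 1L) {
  z <- volData(vol)
  d <- dim(z)
  labels <- array(0L, d)
  claimed <- B
  nextLab <- as.integer(firstLabel)
  # memo for discarded growth: a seed inside a region that was already grown
  # and discarded, with no region accepted since, would regrow it identically
  discardStamp <- array(-1L, d)
  nAccepted <- 0L
  if (nrow(seeds)) {
    idx <- .ijkToInd(as.matrix(seeds[, c("y", "x", "z")]), d)
    for (s in idx) {
      if (claimed[s]) next
      if (discardStamp[s] == nAccepted) next
      reg <- bvgGrow(vol, s, forbidden = claimed, deltaT = deltaT,
                     theta = theta, connectivity = connectivity)
      if (isTRUE(attr(reg, "discarded"))) {   # voxels stay free
        discardStamp[as.integer(reg)] <- nAccepted
        next
      }
      labels[as.integer(reg)] <- nextLab
      claimed[as.integer(reg)] <- TRUE
      nextLab <- nextLab + 1L
      nAccepted <- nAccepted + 1L
    }
  }
  AxonSegmentation(labels, voxelSize(vol))
}
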