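# Internal geometry and array helpers shared across the pipeline.
#
# Axis convention: 3D arrays are indexed (y, x, z) with z the cutting axis;
# voxelSize is the matching (hy, hx, hz) triple in nm. Continuous positions
# are in nm with the centre of voxel (i, j, k) at ((i-1)*hy, (j-1)*hx,
# (k-1)*hz), i.e. a centre-of-voxel convention with the first voxel centre at
# the origin.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertVolumeArray <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
  invisible(x)
}

#' Convert voxel indices to physical coordinates
#'
#' @param ijk integer matrix (n x 3) of 1-based (y, x, z) voxel indices.
#' @param voxelSize numeric(3) voxel size (hy, hx, hz) in nm.
#' @return numeric matrix (n x 3) of positions in nm (centre-of-voxel).
#' @keywords internal
voxelToNm <- function(ijk, voxelSize) {
  ijk <- rbind(ijk)
  sweep(ijk - 1, 2, voxelSize, "*")
}

#' @keywords internal
nmToVoxel <- function(pts, voxelSize) {
  pts <- rbind(pts)
  sweep(pts, 2, voxelSize, "/") + 1
}

# linear (1-based) index <-> (y,x,z) triples
.indToIjk <- function(ind, dims) {
  ind0 <- ind - 1L
  ny <- dims[1L]; nx <- dims[2L]
  k <- ind0 %/% (ny * nx)
  r <- ind0 %% (ny * nx)
  cbind(y = r %% ny + 1L, x = r %/% ny + 1L, z = k + 1L)
}

.ijkToInd <- function(ijk, dims) {
  ijk <- rbind(ijk)
  (ijk[, 1L]) + dims[1L] * (ijk[, 2L] - 1L) + dims[1L] * dims[2L] * (ijk[, 3L] - 1L)
}

#' Trilinear interpolation of a 3D grid at physical positions
#'
#' @param arr 3D numeric array on the (y, x, z) grid.
#' @param pts numeric matrix (n x 3), positions in nm.
#' @param voxelSize numeric(3) in nm.
#' @param outside value used for samples whose support lies outside the grid.
#' @return numeric(n) interpolated values.
#' @keywords internal
trilinearSample <- function(arr, pts, voxelSize, outside = 0) {
  d <- dim(arr)
  f <- nmToVoxel(pts, voxelSize)          # fractional 1-based indices
  i0 <- floor(f)
  fr <- f - i0
  n <- nrow(f)
  out <- numeric(n)
  get <- function(di, dj, dk) {
    ii <- i0[, 1L] + di; jj <- i0[, 2L] + dj; kk <- i0[, 3L] + dk
    ok <- ii >= 1 & ii <= d[1L] & jj >= 1 & jj <= d[2L] & kk >= 1 & kk <= d[3L]
    v <- rep(outside, n)
    if (any(ok))
      v[ok] <- arr[cbind(ii[ok], jj[ok], kk[ok])]
    v
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 1) fr[, 1L] else 1 - fr[, 1L]) *
         (if (dj == 1) fr[, 2L] else 1 - fr[, 2L]) *
         (if (dk == 1) fr[, 3L] else 1 - fr[, 3L])
    out <- out + w * get(di, dj, dk)
  }
  out
}

# central-difference gradient (one-sided at the borders), in physical units
.gradientArrays <- function(arr, voxelSize) {
  d <- dim(arr)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    den <- (hi - lo) * voxelSize[ax]
    idx <- function(sel) switch(ax, arr[sel, , , drop = FALSE],
                                arr[, sel, , drop = FALSE],
                                arr[, , sel, drop = FALSE])
    gr <- (idx(hi) - idx(lo)) / switch(ax,
      array(den, d), array(rep(den, each = d[1L]), d),
      array(rep(den, each = d[1L] * d[2L]), d))
    g[[ax]] <- gr
  }
  names(g) <- c("y", "x", "z")
  g
}

#' Anisotropic Euclidean distance transform
#'
#' Distance, in nm, from every voxel centre to the nearest voxel centre of
#' the target set, honouring the anisotropic voxel size.
#'
#' @param mask logical 3D array, the target set (TRUE voxels).
#' @param voxelSize numeric(3) in nm.
#' @return numeric 3D array of distances (Inf if the mask is empty).
#' @export
distanceTransform <- function(mask, voxelSize) {
  .assertVolumeArray(mask, "mask")
  d <- edt_cpp(as.logical(mask), dim(mask), as.numeric(voxelSize))
  array(d, dim(mask))
}

#' 3D connected components
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26 (face or full neighbourhood).
#' @return integer array of component labels, 0 = background.
#' @export
connectedComponents <- function(mask, connectivity = 26L) {
  .assertVolumeArray(mask, "mask")
  stopifnot(connectivity %in% c(6L, 26L))
  array(cc3d_cpp(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim(mask))
}

#' Fill internal cavities of a 3D mask
#'
#' Complement components not connected to the volume border (6-connectivity)
#' are filled. Used to make an intra-axonal mask solid before
#' skeletonization: unlabelled barrier shells around internal organelles
#' would otherwise count as surface.
#'
#' @param mask logical 3D array.
#' @return logical array with internal holes filled.
#' @export
fillHoles <- function(mask) {
  comp <- connectedComponents(!mask, 6L)
  d <- dim(mask)
  border <- unique(c(comp[c(1L, d[1L]), , ], comp[, c(1L, d[2L]), ],
                     comp[, , c(1L, d[3L])]))
  border <- border[border > 0L]
  mask | (comp > 0L & !(comp %in% border))
}

# run `expr` under a private RNG stream, restoring the caller's state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# separable Gaussian smoothing of a 3D array, sigma per axis in voxels
.gaussianSmooth3d <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- dnorm(seq(-r, r), sd = s)
    kern <- kern / sum(kern)
    arr <- .convolveAxis(arr, kern, ax)
  }
  arr
}

# 1D convolution along an axis with replicated-edge padding
.convolveAxis <- function(arr, kern, ax) {
  d <- dim(arr)
  r <- (length(kern) - 1L) / 2L
  n <- d[ax]
  out <- array(0, d)
  for (t in seq_along(kern)) {
    off <- t - 1L - r
    sel <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(ax, arr[sel, , , drop = FALSE],
                      arr[, sel, , drop = FALSE],
                      arr[, , sel, drop = FALSE])
    out <- out + kern[t] * shifted
  }
  out
}
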