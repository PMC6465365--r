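# Sub-voxel centreline extraction for tubular segments.
#
# The centreline is the minimum-cost path between the two axon tips through
# the deepest interior point. All three key points come from eikonal
# time-of-arrival maps solved by (multi-stencil) fast marching:
#   T1: front from the axon surface at unit speed = distance-to-surface map;
#       its argmax x* is the deepest interior point.
#   F2 = (T1 / T1(x*))^2: a speed that is 1 at the centre and ~0 at the
#       surface, so fronts and minimum-cost paths hug the middle.
#   T2: front from x* at speed F2; argmax = first endpoint e1.
#   T3: front from e1 at speed F2; argmax = second endpoint e2.
# The path is traced from each endpoint by 4th-order Runge-Kutta descent of
# -grad T2 / |grad T2| with a 25 nm step, giving sub-voxel coordinates; the
# two half-paths are joined at x*. Because the endpoints lie on the surface,
# the first micrometre at each end is dropped before morphometry.

#' Solve the eikonal equation |grad T| F = 1 on a voxel domain
#'
#' @param domain logical 3D array of solvable voxels.
#' @param speed positive speed F per voxel (scalar or array).
#' @param sources integer voxel indices (1-based linear) with T = 0.
#' @param voxelSize numeric(3) nm.
#' @param order "msfm" (multi-stencil, second-order; default) or "first".
#' @param exactInit radius (nm) around point sources initialized with the
#'   local closed-form solution, removing the source-singularity error
#'   (which otherwise spreads along the characteristics); default: five
#'   in-plane voxels for a single point source, 0 otherwise.
#' @return numeric array of arrival times (nm when F is dimensionless; Inf
#'   outside the domain or unreached).
#' @export
solveEikonal <- function(domain, speed, sources, voxelSize,
                         order = c("msfm", "first"), exactInit = NULL) {
  order <- match.arg(order)
  d <- dim(domain)
  if (!any(domain)) stop("empty domain")
  if (length(sources) == 0L) stop("empty source set")
  if (length(speed) == 1L) speed <- array(speed, d)
  if (any(speed[domain] <= 0)) stop("speed must be positive on the domain")
  if (is.null(exactInit))
    exactInit <- if (length(sources) == 1L) 5 * voxelSize[1L] else 0
  t <- fmm_cpp(as.logical(domain), as.numeric(speed), d,
               as.numeric(voxelSize), as.integer(sources - 1L),
               if (order == "msfm") 2L else 1L, exactInit)
  array(t, d)
}

# surface voxels of a mask: mask voxels 6-adjacent to a non-mask voxel
# inside the array; faces cut by the array border do not count as surface,
# so tubes running through the whole volume keep open ends
.surfaceVoxels <- function(mask) {
  d <- dim(mask)
  inner <- array(TRUE, d)
  n1 <- d[1L]; n2 <- d[2L]; n3 <- d[3L]
  inner[-1, , ] <- inner[-1, , ] & mask[-n1, , ]
  inner[-n1, , ] <- inner[-n1, , ] & mask[-1, , ]
  inner[, -1, ] <- inner[, -1, ] & mask[, -n2, ]
  inner[, -n2, ] <- inner[, -n2, ] & mask[, -1, ]
  inner[, , -1] <- inner[, , -1] & mask[, , -n3]
  inner[, , -n3] <- inner[, , -n3] & mask[, , -1]
  mask & !inner
}

#' Extract the sub-voxel centreline of an axon segment
#'
#' @param mask logical 3D array: the intra-axonal space of one axon
#'   (mitochondria included), 26-connected, no branches.
#' @param voxelSize numeric(3) nm.
#' @param stepNm backtracking step (default 25 nm).
#' @param trimNm arc length dropped at both ends (default 1000 nm = 1 um).
#' @param axonId id stored on the skeleton.
#' @param order eikonal scheme (see \code{\link{solveEikonal}}).
#' @return a \linkS4class{Skeleton}.
#' @export
extractSkeleton <- function(mask, voxelSize, stepNm = 25, trimNm = 1000,
                            axonId = 1L, order = "msfm") {
  d <- dim(mask)
  if (sum(mask) < 8L) stop("domain too small for skeletonization")
  surf <- .surfaceVoxels(mask)
  if (!any(surf)) stop("domain has no surface (fills the whole array?)")

  T1 <- solveEikonal(mask, 1, which(surf), voxelSize, order = order)
  fin <- is.finite(T1) & mask
  xs <- which.max(ifelse(fin, T1, -Inf))
  t1max <- T1[xs]
  if (t1max <= max(voxelSize))
    stop("domain thinner than two voxels; no interior to skeletonize")

  F2 <- array(1e-3, d)
  F2[fin] <- pmax((T1[fin] / t1max)^2, 1e-3)

  # Endpoint search runs over the core (at least half the maximal interior
  # depth): with the near-zero surface speed, the costliest voxels overall
  # are the *shallow* ones anywhere on the boundary — every pocket is an
  # arrival-time spike — whereas among core voxels the surface-push cost is
  # bounded and the along-tube travel dominates, so the axial tips win
  # robustly. The trimming below compensates for the endpoint's depth.
  deep <- fin & T1 >= 0.5 * t1max
  if (!any(deep)) deep <- fin
  T2 <- solveEikonal(mask, F2, xs, voxelSize, order = order)
  e1 <- which.max(ifelse(is.finite(T2) & deep, T2, -Inf))
  T3 <- solveEikonal(mask, F2, e1, voxelSize, order = order)
  e2 <- which.max(ifelse(is.finite(T3) & deep, T3, -Inf))

  xsNm <- voxelToNm(.indToIjk(xs, d), voxelSize)[1L, ]
  g1 <- .backtrackPath(T2, mask, e1, xs, voxelSize, stepNm)
  g2 <- .backtrackPath(T2, mask, e2, xs, voxelSize, stepNm)
  pts <- rbind(g1, xsNm, g2[rev(seq_len(nrow(g2))), , drop = FALSE])

  seglen <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seglen))
  # drop the first micrometre of axon at each end; detected endpoints already
  # sit T1(e) inside the surface, so the arc removed from the path is the
  # remainder of that micrometre
  trimStart <- max(0, trimNm - T1[e1])
  trimEnd <- max(0, trimNm - T1[e2])
  keep <- arc >= trimStart & arc <= max(arc) - trimEnd
  if (sum(keep) < 2L)
    stop("skeleton shorter than twice the trimming length")
  trimmedPts <- pts[keep, , drop = FALSE]
  arcKeep <- arc[keep] - arc[keep][1L]
  colnames(trimmedPts) <- c("y", "x", "z")
  new("Skeleton", points = trimmedPts, arcLength = arcKeep,
      keyPoints = list(xstar = xsNm,
                       e1 = voxelToNm(.indToIjk(e1, d), voxelSize)[1L, ],
                       e2 = voxelToNm(.indToIjk(e2, d), voxelSize)[1L, ]),
      trimmed = TRUE, axonId = as.integer(axonId))
}

# RK4 descent of -grad T / |grad T| from `from` (voxel index) towards `to`
# (the global minimum of T). Returns points (nm) from the start, exclusive
# of `to`.
.backtrackPath <- function(T2, mask, from, to, voxelSize, stepNm) {
  d <- dim(T2)
  # make T finite outside the domain so interpolated gradients at the
  # boundary point inward
  tg <- T2
  bad <- !is.finite(tg) | !mask
  tmax <- max(tg[!bad])
  tg[bad] <- tmax * 1.05
  g <- .gradientArrays(tg, voxelSize)

  descDir <- function(p) {
    gy <- trilinearSample(g$y, p, voxelSize)
    gx <- trilinearSample(g$x, p, voxelSize)
    gz <- trilinearSample(g$z, p, voxelSize)
    nrm <- sqrt(gy^2 + gx^2 + gz^2)
    if (nrm < 1e-12) return(NULL)
    c(-gy, -gx, -gz) / nrm
  }

  target <- voxelToNm(.indToIjk(to, d), voxelSize)[1L, ]
  p <- voxelToNm(.indToIjk(from, d), voxelSize)[1L, ]
  tol <- 0.5 * max(voxelSize)
  maxSteps <- ceiling(20 * sum(d * voxelSize) / stepNm)
  path <- matrix(NA_real_, maxSteps, 3L)
  nPts <- 0L
  lastT <- trilinearSample(tg, rbind(p), voxelSize)
  bestDist <- Inf
  sinceImprove <- 0L
  for (s in seq_len(maxSteps)) {
    nPts <- nPts + 1L
    path[nPts, ] <- p
    dd <- sqrt(sum((p - target)^2))
    if (dd <= tol) break
    if (dd < bestDist - 1e-9) { bestDist <- dd; sinceImprove <- 0L }
    else sinceImprove <- sinceImprove + 1L
    # near the T2 minimum the interpolated gradient is plateau noise and the
    # descent can orbit the target; once progress stalls within a couple of
    # voxels, snap (x* is appended by the caller)
    if (sinceImprove > 25L) {
      if (dd <= 4 * max(voxelSize)) break
      stop("backtracking stalled ",
           sprintf("%.0f nm from the path origin after %d steps", dd, s))
    }
    k1 <- descDir(rbind(p))
    if (is.null(k1)) k1 <- (target - p) / dd
    k2 <- descDir(rbind(p + stepNm / 2 * k1)) %||% k1
    k3 <- descDir(rbind(p + stepNm / 2 * k2)) %||% k2
    k4 <- descDir(rbind(p + stepNm * k3)) %||% k3
    p <- p + stepNm / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    curT <- trilinearSample(tg, rbind(p), voxelSize)
    if (curT > lastT + 1e-6 * tmax) {
      # gradient noise at plateau scale: nudge straight towards the minimum
      p <- path[nPts, ] + stepNm * (target - path[nPts, ]) /
        sqrt(sum((target - path[nPts, ])^2))
      curT <- trilinearSample(tg, rbind(p), voxelSize)
    }
    lastT <- curT
    if (s == maxSteps)
      stop("backtracking did not reach the path origin (",
           sprintf("%.0f nm away after %d steps)",
                   sqrt(sum((p - target)^2)), s))
  }
  path[seq_len(nPts), , drop = FALSE]
}
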