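# Perpendicular cross-sections along the skeleton and moment-based shape
# measures. At each skeleton point the plane normal to the local tangent is
# sampled on an 8 um x 8 um frame at 50 nm spacing by trilinear
# interpolation of the binary axon mask; values >= 0.5 are foreground and
# only the connected component at the frame centre is kept. The ellipse
# with the same normalized second central moments as the section yields the
# minor/major axes and eccentricity; the equivalent diameter is that of the
# circle with the section's area.

#' Ellipse parameters from second central moments
#'
#' Given central second moments (mu20, mu02, mu11; same length^2 units) and
#' the region area, returns the axes of the ellipse with identical
#' normalized second moments: full axis length 4 * sqrt(eigenvalue). For a
#' continuous circle of radius r (mu20 = mu02 = r^2/4) this gives minor =
#' major = 2r and eccentricity exactly 0.
#'
#' @param mu20,mu02,mu11 normalized (per-area) central second moments.
#' @param area region area (same length unit squared).
#' @return data.frame with minor_axis, major_axis, eccentricity,
#'   equivalent_diameter, area.
#' @export
ellipseFromMoments <- function(mu20, mu02, mu11, area) {
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(pmax((tr / 2)^2 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- pmax(tr / 2 - disc, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- sqrt(pmax(1 - ifelse(major > 0, (minor / major)^2, 1), 0))
  data.frame(minor_axis = minor, major_axis = major, eccentricity = ecc,
             equivalent_diameter = 2 * sqrt(area / pi), area = area)
}

#' Measure a binary 2D section by moment-matched ellipse
#'
#' Pixel second moments include the per-axis 1/12 cell-variance term, so a
#' rasterized shape reproduces its continuous moments as the grid refines.
#'
#' @param maskMat logical matrix (rows = first axis, cols = second axis).
#' @param cellSize numeric(2) pixel size along (rows, cols), in nm.
#' @return one-row data.frame as \code{\link{ellipseFromMoments}} (nm units);
#'   NULL if the section is empty.
#' @export
measureBinarySection <- function(maskMat, cellSize) {
  w <- which(maskMat, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  u <- (w[, 1L] - 1) * cellSize[1L]
  v <- (w[, 2L] - 1) * cellSize[2L]
  du <- u - mean(u)
  dv <- v - mean(v)
  mu20 <- mean(du^2) + cellSize[1L]^2 / 12
  mu02 <- mean(dv^2) + cellSize[2L]^2 / 12
  mu11 <- mean(du * dv)
  area <- nrow(w) * cellSize[1L] * cellSize[2L]
  ellipseFromMoments(mu20, mu02, mu11, area)
}

# deterministic orthonormal in-plane basis for a unit normal: Householder
# construction from the coordinate axis least aligned with the tangent
.frameBasis <- function(tangent) {
  t <- tangent / sqrt(sum(tangent^2))
  e <- c(0, 0, 0)
  e[which.min(abs(t))] <- 1
  u <- e - sum(e * t) * t
  u <- u / sqrt(sum(u^2))
  v <- c(t[2L] * u[3L] - t[3L] * u[2L],
         t[3L] * u[1L] - t[1L] * u[3L],
         t[1L] * u[2L] - t[2L] * u[1L])
  list(u = u, v = v)
}

#' Sample the cross-section of an axon mask at a skeleton point
#'
#' @param mask logical 3D axon mask.
#' @param voxelSize numeric(3) nm.
#' @param point numeric(3) (y, x, z) position in nm on the skeleton.
#' @param tangent numeric(3) unit tangent of the skeleton at that point.
#' @param frameNm frame side length (default 8000 nm).
#' @param spacingNm frame resolution (default 50 nm).
#' @return list of class \code{CrossSection}: logical matrix \code{C},
#'   \code{origin}, \code{tangent}, basis \code{u}, \code{v},
#'   \code{spacing}; \code{empty} flag when no foreground survives the
#'   centre-component filter.
#' @export
sampleCrossSection <- function(mask, voxelSize, point, tangent,
                               frameNm = 8000, spacingNm = 50) {
  nGrid <- round(frameNm / spacingNm)
  off <- (seq_len(nGrid) - (nGrid + 1) / 2) * spacingNm
  basis <- .frameBasis(tangent)
  U <- matrix(off, nGrid, nGrid)
  V <- matrix(off, nGrid, nGrid, byrow = TRUE)
  pts <- cbind(as.numeric(point[1L] + U * basis$u[1L] + V * basis$v[1L]),
               as.numeric(point[2L] + U * basis$u[2L] + V * basis$v[2L]),
               as.numeric(point[3L] + U * basis$u[3L] + V * basis$v[3L]))
  vals <- trilinearSample(mask + 0, pts, voxelSize, outside = 0)
  C <- matrix(vals >= 0.5, nGrid, nGrid)
  empty <- TRUE
  if (any(C)) {
    lab <- connectedComponents(array(C, c(nGrid, nGrid, 1L)), 26L)[, , 1L]
    ctr <- nGrid %/% 2 + c(0L, 1L)
    centreLabs <- lab[ctr, ctr]
    keep <- centreLabs[centreLabs > 0L][1L]
    if (!is.na(keep)) {
      C <- lab == keep
      empty <- FALSE
    } else C[] <- FALSE
  } else C[] <- FALSE
  structure(list(C = C, origin = point, tangent = tangent, u = basis$u,
                 v = basis$v, spacing = spacingNm, empty = empty),
            class = "CrossSection")
}

#' Measure a cross-section
#'
#' @param cs a \code{CrossSection}.
#' @return one-row data.frame (nm units), or NULL for an empty section.
#' @export
measureCrossSection <- function(cs) {
  if (isTRUE(cs$empty)) return(NULL)
  measureBinarySection(cs$C, c(cs$spacing, cs$spacing))
}

#' Skeleton tangents
#'
#' Central differences over a +/- \code{window}-point span (250 nm at the
#' default 25 nm step), renormalized; single-step differences would be noisy
#' at sub-voxel step sizes.
#'
#' @param skel a \linkS4class{Skeleton}.
#' @param window half-window in points (default 5).
#' @return matrix (n x 3) of unit tangents.
#' @export
skeletonTangents <- function(skel, window = 5L) {
  p <- skelPoints(skel)
  n <- nrow(p)
  lo <- pmax(seq_len(n) - window, 1L)
  hi <- pmin(seq_len(n) + window, n)
  tg <- p[hi, , drop = FALSE] - p[lo, , drop = FALSE]
  nrm <- sqrt(rowSums(tg^2))
  nrm[nrm == 0] <- 1
  tg / nrm
}

#' Morphometry of one axon along its skeleton
#'
#' Cross-sections are measured at every skeleton point (25 nm apart); the
#' per-axon summary is the median of each measure. The axon is included in
#' group statistics only if its skeleton is at least \code{lengthMinUm}
#' long. The mask should contain the intra-axonal space with mitochondria
#' included and vacuoles excluded.
#'
#' @param mask logical 3D axon mask.
#' @param skel its \linkS4class{Skeleton} (trimmed).
#' @param voxelSize numeric(3) nm.
#' @param lengthMinUm length filter in micrometres (default 5).
#' @param every measure every k-th skeleton point (default 1).
#' @return list of class \code{AxonMorphometry}: \code{axonId},
#'   \code{series} (per-point data.frame with arc_length_um), \code{medians},
#'   \code{lengthUm}, \code{included}, \code{nEmpty}.
#' @export
axonMorphometry <- function(mask, skel, voxelSize, lengthMinUm = 5,
                            every = 1L) {
  p <- skelPoints(skel)
  if (nrow(p) < 2L) stop("skeleton too short for morphometry")
  tg <- skeletonTangents(skel)
  sel <- seq(1L, nrow(p), by = every)
  rows <- vector("list", length(sel))
  nEmpty <- 0L
  for (ii in seq_along(sel)) {
    i <- sel[ii]
    cs <- sampleCrossSection(mask, voxelSize, p[i, ], tg[i, ])
    m <- measureCrossSection(cs)
    if (is.null(m)) { nEmpty <- nEmpty + 1L; next }
    m$point_index <- i
    m$arc_length_um <- skel@arcLength[i] / 1000
    rows[[ii]] <- m
  }
  series <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  lengthUm <- skelLength(skel)
  meas <- c("minor_axis", "major_axis", "eccentricity",
            "equivalent_diameter", "area")
  medians <- if (!is.null(series))
    vapply(series[meas], stats::median, numeric(1L))
  else stats::setNames(rep(NA_real_, length(meas)), meas)
  structure(list(axonId = skel@axonId, series = series, medians = medians,
                 lengthUm = lengthUm, included = lengthUm >= lengthMinUm,
                 nEmpty = nEmpty),
            class = "AxonMorphometry")
}
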