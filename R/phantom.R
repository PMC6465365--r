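# Synthetic SBEM-like phantoms with ground truth.
#
# The generator emulates the appearance of white-matter SBEM data: dark
# myelin sheaths wrapped around brighter intra-axonal lumens, dark
# intra-axonal mitochondria, very bright vacuoles, unmyelinated axons, one
# large cell-body region, additive Gaussian noise, and the acquisition
# anisotropy (in-plane ~15 nm, 50 nm sections). Axon centrelines wiggle
# laterally and radii vary sinusoidally along the axis, so downstream
# morphometry sees a varying diameter, as real axons do.

.phantomDefaultAxons <- function() {
  list(
    list(center = c(760, 760),   radius = 250, radiusAmp = 0.15,
         radiusPeriod = 3000, wiggleAmp = 50, wigglePeriod = 6000,
         phase = 0.0, myelinated = TRUE,  sheath = 190),
    list(center = c(760, 1660),  radius = 300, radiusAmp = 0.12,
         radiusPeriod = 4000, wiggleAmp = 40, wigglePeriod = 6000,
         phase = 1.3, myelinated = TRUE,  sheath = 170),
    list(center = c(1660, 760),  radius = 200, radiusAmp = 0.18,
         radiusPeriod = 2500, wiggleAmp = 50, wigglePeriod = 6000,
         phase = 2.1, myelinated = TRUE,  sheath = 210),
    list(center = c(1660, 1660), radius = 340, radiusAmp = 0.10,
         radiusPeriod = 5000, wiggleAmp = 40, wigglePeriod = 6000,
         phase = 4.0, myelinated = TRUE,  sheath = 190),
    list(center = c(350, 2300),  radius = 150, radiusAmp = 0.10,
         radiusPeriod = 3000, wiggleAmp = 30, wigglePeriod = 6000,
         phase = 0.7, myelinated = FALSE, sheath = 0),
    list(center = c(2300, 350),  radius = 180, radiusAmp = 0.10,
         radiusPeriod = 3500, wiggleAmp = 30, wigglePeriod = 6000,
         phase = 2.9, myelinated = FALSE, sheath = 0)
  )
}

#' Specification of a synthetic white-matter SBEM phantom
#'
#' Defaults produce a 2.7 x 2.7 x 6 um volume at 15 x 15 x 50 nm voxels with
#' four myelinated axons whose sheaths touch (myelin forms one connected
#' structure), two unmyelinated axons, two mitochondria, two vacuoles and a
#' cell-body blob. Class intensity means are ordered as in the data the
#' pipeline targets: myelin and mitochondria dark, axoplasm intermediate,
#' vacuoles very bright.
#'
#' @param shape integer(3) volume shape (ny, nx, nz) in voxels.
#' @param voxelSize numeric(3) (hy, hx, hz) in nm.
#' @param axons list of axon descriptors (center nm, radius nm, radiusAmp
#'   fraction, radiusPeriod nm, wiggleAmp nm, wigglePeriod nm, phase,
#'   myelinated, sheath thickness nm).
#' @param mitochondria list of (axon = parent index, z = axial position nm,
#'   radius nm, halfLength nm).
#' @param vacuoles list of (center = c(y, x, z) nm, radius nm).
#' @param cellRegion NULL or list(center = c(y, x, z) nm, semiAxes = c(ry,
#'   rx, rz) nm).
#' @param intensityMeans named numeric: myelin, mitochondrion, axoplasm,
#'   vacuole, cell, background, membrane (all in [0, 1]).
#' @param membraneNm thickness of the dark plasma-membrane rind drawn around
#'   unmyelinated axons, vacuoles and the cell region (nm). Membrane voxels
#'   carry ground-truth label 0 (boundary, not intra-cellular space).
#' @param noiseSigma additive Gaussian noise SD (dimensionless intensity).
#' @param seed RNG seed making the phantom deterministic.
#' @return a list usable by \code{\link{generatePhantom}}.
#' @export
phantomSpec <- function(shape = c(180L, 180L, 120L),
                        voxelSize = c(15, 15, 50),
                        axons = .phantomDefaultAxons(),
                        mitochondria = list(
                          list(axon = 1L, z = 2000, radius = 110, halfLength = 450),
                          list(axon = 4L, z = 4200, radius = 130, halfLength = 500)),
                        vacuoles = list(
                          list(center = c(330, 1150, 1400), radius = 290),
                          list(center = c(2370, 1500, 4300), radius = 280)),
                        cellRegion = list(center = c(2380, 2380, 3000),
                                          semiAxes = c(620, 620, 2800)),
                        intensityMeans = c(myelin = 0.20, mitochondrion = 0.22,
                                           axoplasm = 0.60, vacuole = 0.92,
                                           cell = 0.45, background = 0.75,
                                           membrane = 0.35),
                        membraneNm = 35,
                        noiseSigma = 0.08,
                        seed = 1L) {
  m <- intensityMeans
  if (m[["vacuole"]] < 0.85) stop("vacuole mean must be >= 0.85")
  if (m[["myelin"]] > 0.4) stop("myelin mean must be <= 0.4")
  if (!(m[["myelin"]] < m[["axoplasm"]] && m[["axoplasm"]] < m[["vacuole"]]))
    stop("class means must be ordered myelin < axoplasm < vacuole")
  for (ax in axons) if (ax$radius <= 0) stop("axon radius must be positive")
  list(shape = as.integer(shape), voxelSize = as.numeric(voxelSize),
       axons = axons, mitochondria = mitochondria, vacuoles = vacuoles,
       cellRegion = cellRegion, intensityMeans = m, membraneNm = membraneNm,
       noiseSigma = noiseSigma, seed = as.integer(seed))
}

# centreline and radius of axon `ax` at axial position z (nm)
.axonProfile <- function(ax, z) {
  y0 <- ax$center[1L] + ax$wiggleAmp * sin(2 * pi * z / ax$wigglePeriod + ax$phase)
  x0 <- ax$center[2L] + ax$wiggleAmp * cos(2 * pi * z / ax$wigglePeriod + ax$phase)
  r <- ax$radius * (1 + ax$radiusAmp * sin(2 * pi * z / ax$radiusPeriod + ax$phase))
  list(y = y0, x = x0, r = r)
}

#' Generate a synthetic SBEM phantom with ground truth
#'
#' Builds the class template (per-class mean intensity), adds Gaussian noise
#' of SD \code{noiseSigma}, clips to [0, 1], and returns the volume together
#' with a ground-truth segmentation: one MYELIN segment (all sheaths merged,
#' mitochondria excluded), one segment per axon lumen, per mitochondrion
#' (with its parent axon), per vacuole, and per cell region.
#'
#' @param spec a list from \code{\link{phantomSpec}}.
#' @return list with elements \code{volume} (\linkS4class{SBEMVolume}),
#'   \code{truth} (\linkS4class{AxonSegmentation}) and \code{spec}.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  d <- spec$shape
  vs <- spec$voxelSize
  ny <- d[1L]; nx <- d[2L]; nz <- d[3L]
  m <- spec$intensityMeans

  Y <- matrix((seq_len(ny) - 1) * vs[1L], ny, nx)
  X <- matrix((seq_len(nx) - 1) * vs[2L], ny, nx, byrow = TRUE)

  template <- array(m[["background"]], d)
  labels <- array(0L, d)
  nAx <- length(spec$axons)

  # label ids: 1 = myelin; 2..(1+nAx) = axon lumens; then mitochondria,
  # vacuoles, cells
  mitoId0 <- 1L + nAx
  vacId0 <- mitoId0 + length(spec$mitochondria)
  cellId <- vacId0 + length(spec$vacuoles) + 1L  # single cell region id

  tm <- spec$membraneNm %||% 0
  memb <- if ("membrane" %in% names(m)) m[["membrane"]] else m[["myelin"]]

  # cell region first (lowest priority); a thin dark membrane rind surrounds
  # it (label 0: boundary, not intra-cellular space)
  if (!is.null(spec$cellRegion)) {
    cr <- spec$cellRegion
    for (k in seq_len(nz)) {
      z <- (k - 1) * vs[3L]
      zfm <- ((z - cr$center[3L]) / (cr$semiAxes[3L] + tm))^2
      if (zfm <= 1) {
        mskM <- ((Y - cr$center[1L]) / (cr$semiAxes[1L] + tm))^2 +
                ((X - cr$center[2L]) / (cr$semiAxes[2L] + tm))^2 <= 1 - zfm
        sl <- template[, , k]; sl[mskM] <- memb; template[, , k] <- sl
      }
      zf <- ((z - cr$center[3L]) / cr$semiAxes[3L])^2
      if (zf > 1) next
      msk <- ((Y - cr$center[1L]) / cr$semiAxes[1L])^2 +
             ((X - cr$center[2L]) / cr$semiAxes[2L])^2 <= 1 - zf
      sl <- template[, , k]; sl[msk] <- m[["cell"]]; template[, , k] <- sl
      lb <- labels[, , k]; lb[msk] <- cellId; labels[, , k] <- lb
    }
  }

  # vacuoles, each wrapped in a membrane rind
  for (vi in seq_along(spec$vacuoles)) {
    v <- spec$vacuoles[[vi]]
    for (k in seq_len(nz)) {
      z <- (k - 1) * vs[3L]
      zf <- (z - v$center[3L])^2
      if (zf <= (v$radius + tm)^2) {
        mskM <- (Y - v$center[1L])^2 + (X - v$center[2L])^2 <=
          (v$radius + tm)^2 - zf
        sl <- template[, , k]; sl[mskM] <- memb; template[, , k] <- sl
      }
      if (zf > v$radius^2) next
      r2 <- v$radius^2 - zf
      msk <- (Y - v$center[1L])^2 + (X - v$center[2L])^2 <= r2
      if (!any(msk)) next
      sl <- template[, , k]; sl[msk] <- m[["vacuole"]]; template[, , k] <- sl
      lb <- labels[, , k]; lb[msk] <- vacId0 + vi; labels[, , k] <- lb
    }
  }

  # axons: sheaths first (all axons), then lumens, so touching sheaths merge;
  # unmyelinated axons get a membrane rind instead of a myelin sheath
  for (pass in c("sheath", "lumen")) {
    for (ai in seq_len(nAx)) {
      ax <- spec$axons[[ai]]
      for (k in seq_len(nz)) {
        z <- (k - 1) * vs[3L]
        pr <- .axonProfile(ax, z)
        dist2 <- (Y - pr$y)^2 + (X - pr$x)^2
        if (pass == "sheath") {
          if (ax$myelinated && ax$sheath > 0) {
            msk <- dist2 <= (pr$r + ax$sheath)^2
            val <- m[["myelin"]]; id <- 1L
          } else {
            msk <- dist2 <= (pr$r + tm)^2
            val <- memb; id <- 0L
          }
        } else {
          msk <- dist2 <= pr$r^2
          val <- m[["axoplasm"]]; id <- 1L + ai
        }
        if (!any(msk)) next
        if (pass == "lumen") {
          lb <- labels[, , k]
          clash <- msk & lb > 1L & lb <= 1L + nAx & lb != id
          if (any(clash)) stop("axon lumens/sheaths overlap: adjust the spec")
        }
        sl <- template[, , k]; sl[msk] <- val; template[, , k] <- sl
        lb <- labels[, , k]; lb[msk] <- id; labels[, , k] <- lb
      }
    }
  }

  # mitochondria inside their parent lumen
  for (mi in seq_along(spec$mitochondria)) {
    mt <- spec$mitochondria[[mi]]
    ax <- spec$axons[[mt$axon]]
    id <- mitoId0 + mi
    for (k in seq_len(nz)) {
      z <- (k - 1) * vs[3L]
      zf <- ((z - mt$z) / mt$halfLength)^2
      if (zf > 1) next
      pr <- .axonProfile(ax, z)
      r2 <- mt$radius^2 * (1 - zf)
      msk <- (Y - pr$y)^2 + (X - pr$x)^2 <= r2
      lb <- labels[, , k]
      msk <- msk & lb == (1L + mt$axon)  # stay inside the lumen
      if (!any(msk)) next
      sl <- template[, , k]; sl[msk] <- m[["mitochondrion"]]; template[, , k] <- sl
      lb[msk] <- id; labels[, , k] <- lb
    }
  }

  noisy <- if (spec$noiseSigma > 0) {
    withSeed(spec$seed, template + array(stats::rnorm(prod(d), 0, spec$noiseSigma), d))
  } else template
  noisy <- pmin(pmax(noisy, 0), 1)
  dim(noisy) <- d

  # ground-truth segment table
  tab <- data.frame(id = integer(0), klass = character(0),
                    voxel_count = integer(0), parent_axon_id = integer(0),
                    review_flag = logical(0), stringsAsFactors = FALSE)
  addRow <- function(id, klass, parent = NA_integer_) {
    cnt <- sum(labels == id)
    if (cnt == 0L) return(invisible())
    tab <<- rbind(tab, data.frame(id = id, klass = klass, voxel_count = cnt,
                                  parent_axon_id = parent, review_flag = FALSE,
                                  stringsAsFactors = FALSE))
  }
  addRow(1L, "MYELIN")
  for (ai in seq_len(nAx))
    addRow(1L + ai, if (spec$axons[[ai]]$myelinated) "MYELINATED_AXON"
                    else "UNMYELINATED_AXON")
  for (mi in seq_along(spec$mitochondria))
    addRow(mitoId0 + mi, "MITOCHONDRION",
           parent = 1L + spec$mitochondria[[mi]]$axon)
  for (vi in seq_along(spec$vacuoles)) addRow(vacId0 + vi, "VACUOLE")
  addRow(cellId, "CELL")

  list(volume = SBEMVolume(noisy, vs),
       truth = AxonSegmentation(labels, vs, tab),
       spec = spec)
}

#' Voxelize a straight circular cylinder at a known tilt
#'
#' A fixture with closed-form geometry: the cylinder axis passes through the
#' volume centre and makes \code{tilt} degrees with the z (cutting) axis,
#' tilted within the x-z plane. The true perpendicular cross-section is a
#' circle of diameter 2*radius; the in-plane (x-y) section is an ellipse with
#' minor 2*radius and major 2*radius/cos(tilt).
#'
#' @param radius cylinder radius in nm.
#' @param tilt tilt from the z axis in degrees (must be < 90).
#' @param length cylinder length in nm (along its axis).
#' @param shape integer(3) (ny, nx, nz) volume shape.
#' @param voxelSize numeric(3) in nm.
#' @param lumenMean,backgroundMean template intensities.
#' @return list with \code{volume}, logical \code{mask}, \code{center} (nm),
#'   unit \code{direction} (y, x, z), \code{radius}, \code{length}, and the
#'   analytic in-plane ellipse axes \code{inPlaneMinor}, \code{inPlaneMajor}.
#' @export
analyticCylinder <- function(radius, tilt, length, shape = c(80L, 80L, 200L),
                             voxelSize = c(15, 15, 50),
                             lumenMean = 0.6, backgroundMean = 0.2) {
  if (tilt >= 90) stop("tilt must be below 90 degrees")
  d <- as.integer(shape); vs <- as.numeric(voxelSize)
  tiltRad <- tilt * pi / 180
  dir <- c(0, sin(tiltRad), cos(tiltRad))       # (y, x, z), unit length
  center <- (d - 1) * vs / 2

  ext <- c((d[1L] - 1) * vs[1L], (d[2L] - 1) * vs[2L])
  lat <- abs(length / 2 * dir[1:2]) + radius
  if (any(center[1:2] - lat < -vs[1:2]) || any(center[1:2] + lat > ext + vs[1:2]))
    stop("cylinder exceeds the lateral volume bounds")

  co <- .gridCoordinates(d, vs)
  py <- co$Y - center[1L]; px <- co$X - center[2L]; pz <- co$Z - center[3L]
  axial <- py * dir[1L] + px * dir[2L] + pz * dir[3L]
  perp2 <- (py - axial * dir[1L])^2 + (px - axial * dir[2L])^2 +
           (pz - axial * dir[3L])^2
  mask <- perp2 <= radius^2 & abs(axial) <= length / 2
  dim(mask) <- d

  template <- array(backgroundMean, d)
  template[mask] <- lumenMean
  list(volume = SBEMVolume(template, vs), mask = mask, center = center,
       direction = dir, radius = radius, length = length,
       inPlaneMinor = 2 * radius, inPlaneMajor = 2 * radius / cos(tiltRad))
}

# full-grid physical coordinate arrays (nm)
.gridCoordinates <- function(d, vs) {
  list(Y = array((seq_len(d[1L]) - 1) * vs[1L], d),
       X = array(rep((seq_len(d[2L]) - 1) * vs[2L], each = d[1L]), d),
       Z = array(rep((seq_len(d[3L]) - 1) * vs[3L], each = d[1L] * d[2L]), d))
}

#' Voxelize a tube around a polyline centreline
#'
#' Exact point-to-segment distances (no rasterization of the centreline), so
#' the tube radius is unbiased; intended for bent-tube and tilted-tube test
#' geometries.
#'
#' @param vertices numeric matrix (m x 3) of (y, x, z) centreline vertices in
#'   nm.
#' @param radius tube radius in nm.
#' @param shape integer(3) volume shape.
#' @param voxelSize numeric(3) nm.
#' @return logical 3D array.
#' @export
polylineTubeMask <- function(vertices, radius, shape, voxelSize) {
  d <- as.integer(shape); vs <- as.numeric(voxelSize)
  co <- .gridCoordinates(d, vs)
  best2 <- array(Inf, d)
  for (s in seq_len(nrow(vertices) - 1L)) {
    a <- vertices[s, ]; b <- vertices[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((co$Y - a[1L]) * ab[1L] + (co$X - a[2L]) * ab[2L] +
          (co$Z - a[3L]) * ab[3L]) / len2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (co$Y - a[1L] - t * ab[1L])^2 + (co$X - a[2L] - t * ab[2L])^2 +
          (co$Z - a[3L] - t * ab[3L])^2
    best2 <- pmin(best2, d2)
  }
  m <- best2 <= radius^2
  dim(m) <- d
  m
}
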