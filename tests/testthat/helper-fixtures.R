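# Shared fixture builders (all generated in code; nothing on disk).

# capsule (segment + spherical caps) along z through the volume centre
capsuleMask <- function(radius = 400, tipLength = 10000,
                        shape = c(64L, 64L, 232L), voxelSize = c(15, 15, 50)) {
  ctr <- (shape - 1) * voxelSize / 2
  half <- tipLength / 2 - radius
  polylineTubeMask(rbind(c(ctr[1], ctr[2], ctr[3] - half),
                         c(ctr[1], ctr[2], ctr[3] + half)),
                   radius, shape, voxelSize)
}

# straight elliptical cylinder along z (axes in nm), per-slice rasterization
ellipticalCylinderMask <- function(a = 540, b = 400, shape = c(90L, 90L, 80L),
                                   voxelSize = c(15, 15, 50)) {
  ny <- shape[1L]; nx <- shape[2L]
  cy <- (ny - 1) * voxelSize[1L] / 2
  cx <- (nx - 1) * voxelSize[2L] / 2
  Y <- matrix((seq_len(ny) - 1) * voxelSize[1L], ny, nx)
  X <- matrix((seq_len(nx) - 1) * voxelSize[2L], ny, nx, byrow = TRUE)
  sl <- ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
  array(sl, shape)
}

# small two-axon phantom for pipeline-level tests (cheap to segment)
smallPhantomSpec <- function(noiseSigma = 0, seed = 1L) {
  phantomSpec(
    shape = c(130L, 130L, 70L),
    axons = list(
      list(center = c(650, 650), radius = 250, radiusAmp = 0.1,
           radiusPeriod = 3000, wiggleAmp = 30, wigglePeriod = 6000,
           phase = 0, myelinated = TRUE, sheath = 210),
      list(center = c(650, 1330), radius = 280, radiusAmp = 0.1,
           radiusPeriod = 3500, wiggleAmp = 30, wigglePeriod = 6000,
           phase = 2, myelinated = TRUE, sheath = 200)),
    mitochondria = list(),
    vacuoles = list(),
    cellRegion = NULL,
    noiseSigma = noiseSigma, seed = seed)
}

rasterDisk <- function(r, cell = 50, n = 81) {
  off <- (seq_len(n) - (n + 1) / 2) * cell
  U <- matrix(off, n, n)
  V <- matrix(off, n, n, byrow = TRUE)
  U^2 + V^2 <= r^2
}

rasterEllipse <- function(a, b, theta = 0, cell = 50, n = 81) {
  off <- (seq_len(n) - (n + 1) / 2) * cell
  U <- matrix(off, n, n)
  V <- matrix(off, n, n, byrow = TRUE)
  x <- cos(theta) * U + sin(theta) * V
  y <- -sin(theta) * U + cos(theta) * V
  (x / a)^2 + (y / b)^2 <= 1
}

# hierarchical normal data: group/animal/axon/cross-section
nestedData <- function(nGroups = 2, nAnimals = 3, nAxons = 10, nCross = 20,
                       sdAnimal = 1, sdAxon = 1, sdCross = 1,
                       groupShift = 0, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (g in seq_len(nGroups)) {
    for (an in seq_len(nAnimals)) {
      muAn <- (g - 1) * groupShift + rnorm(1, 0, sdAnimal)
      for (ax in seq_len(nAxons)) {
        muAx <- muAn + rnorm(1, 0, sdAxon)
        rows[[length(rows) + 1L]] <- data.frame(
          group = paste0("g", g),
          animal = paste0("g", g, "a", an),
          axon = paste0("g", g, "a", an, "x", ax),
          value = muAx + rnorm(nCross, 0, sdCross))
      }
    }
  }
  do.call(rbind, rows)
}
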