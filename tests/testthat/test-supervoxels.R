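test_that("supervoxels fully partition the volume into compact cells", {
  vol <- SBEMVolume(array(0.5, c(40, 40, 12)), c(15, 15, 50))
  sv <- computeSupervoxels(vol, step = 8)
  expect_identical(sum(tabulate(sv$labels, sv$Q)), length(sv$labels))
  expect_true(all(sv$labels >= 1L & sv$labels <= sv$Q))
  # constant volume: spatial term dominates, bounding boxes within 2*rho
  # per scaled axis
  w <- which(array(TRUE, dim(sv$labels)), arr.ind = TRUE)
  spacing <- c(1, 1, 50 / 15)
  for (q in sample.int(sv$Q, 12L)) {
    sel <- sv$labels == q
    bb <- apply(w[sel, , drop = FALSE], 2, function(v) diff(range(v)))
    expect_true(all(bb * spacing <= 2 * 8 + 1e-9))
  }
})

test_that("supervoxels respect a two-intensity boundary", {
  d <- c(36L, 36L, 9L)
  z <- array(0.3, d)
  z[, 19:36, ] <- 0.7
  vol <- SBEMVolume(z, c(15, 15, 50))
  sv <- computeSupervoxels(vol, step = 6)
  # no supervoxel straddles the boundary by more than one voxel depth
  violations <- 0L
  for (q in seq_len(sv$Q)) {
    cols <- which(sv$labels == q, arr.ind = TRUE)[, 2L]
    if (any(cols <= 18L) && any(cols >= 19L) &&
        !(min(cols) >= 18L || max(cols) <= 19L))
      violations <- violations + 1L
  }
  expect_identical(violations, 0L)
})

test_that("refinement is a fixed point for supervoxel-aligned labels", {
  vol <- SBEMVolume(array(0.5, c(30, 30, 9)), c(15, 15, 50))
  sv <- computeSupervoxels(vol, step = 5)
  labels <- array(0L, dim(sv$labels))
  pick <- seq_len(floor(sv$Q / 2))
  labels[sv$labels %in% pick] <- 1L
  seg <- AxonSegmentation(labels, c(15, 15, 50))
  ref <- refineLabels(seg, sv, minLarge = 10)
  expect_identical(labelData(ref), labels)
})

test_that("the 0.8 claiming threshold is inclusive and half-overlap is not enough", {
  # hand-built partition: two supervoxels of 10 voxels each in a 20-voxel bar
  labelsSv <- array(rep(c(1L, 2L), each = 10L), c(20L, 1L, 1L))
  sv <- structure(list(labels = labelsSv, Q = 2L, params = list()),
                  class = "SupervoxelPartition")
  mk <- function(n1, n2) {
    lab <- array(0L, c(20L, 1L, 1L))
    if (n1 > 0) lab[seq_len(n1), 1, 1] <- 1L
    if (n2 > 0) lab[10L + seq_len(n2), 1, 1] <- 1L
    AxonSegmentation(lab, c(15, 15, 50))
  }
  # exactly 0.8 of supervoxel 2 -> claimed (ties count)
  ref <- refineLabels(mk(10L, 8L), sv, minLarge = 1)
  expect_identical(sum(labelData(ref) == 1L), 20L)
  # half of supervoxel 2 -> not claimed, but grown voxels are kept
  ref <- refineLabels(mk(10L, 5L), sv, minLarge = 1)
  expect_identical(sum(labelData(ref) == 1L), 15L)
})

test_that("refinement claims serially and never merges two large segments", {
  labelsSv <- array(rep(1:3, each = 12L), c(36L, 1L, 1L))
  sv <- structure(list(labels = labelsSv, Q = 3L, params = list()),
                  class = "SupervoxelPartition")
  lab <- array(0L, c(36L, 1L, 1L))
  lab[1:12, 1, 1] <- 1L          # owns supervoxel 1
  lab[13:23, 1, 1] <- 1L         # 11/12 of supervoxel 2 -> id 1 claims it
  lab[24, 1, 1] <- 2L            # id 2 has a toehold there too
  lab[25:36, 1, 1] <- 2L         # owns supervoxel 3
  seg <- AxonSegmentation(lab, c(15, 15, 50))
  ref <- refineLabels(seg, sv, minLarge = 1)
  out <- labelData(ref)
  expect_identical(sum(out == 1L), 24L)   # claimed whole supervoxel 2
  expect_identical(sum(out == 2L), 12L)
  expect_identical(length(unique(out[out > 0])), 2L)
})

test_that("small volumes dissolve and labelled count never increases", {
  labelsSv <- array(rep(1:2, each = 10L), c(20L, 1L, 1L))
  sv <- structure(list(labels = labelsSv, Q = 2L, params = list()),
                  class = "SupervoxelPartition")
  lab <- array(0L, c(20L, 1L, 1L))
  lab[1:9, 1, 1] <- 1L            # large (minLarge = 5)
  lab[15:16, 1, 1] <- 2L          # small -> dissolves
  seg <- AxonSegmentation(lab, c(15, 15, 50))
  ref <- refineLabels(seg, sv, minLarge = 5)
  out <- labelData(ref)
  expect_identical(sort(unique(as.integer(out[out > 0]))), 1L)
  expect_lte(length(unique(out[out > 0])),
             length(unique(lab[lab > 0])))
})
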