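test_that("closing fills sub-radius cavities and leaves larger ones open", {
  vs <- c(25, 25, 50)
  shape <- c(100L, 100L, 100L)
  ctr <- (shape - 1) * vs / 2
  solid <- polylineTubeMask(rbind(c(ctr[1], ctr[2], 400),
                                  c(ctr[1], ctr[2], 4600)), 900, shape, vs)
  # solid tube: closing is (near-)identity, no real cavity candidates
  mito <- detectMitochondria(solid, NULL, vs, closingRadius = 1000)
  expect_lt(length(unlist(mito)), 0.002 * sum(solid))
  expect_true(attr(mito, "review_flag"))

  co <- axomorph:::.gridCoordinates(shape, vs)
  cav <- sqrt((co$Y - ctr[1])^2 + (co$X - ctr[2])^2 + (co$Z - 2500)^2) <= 400
  withCavity <- solid & !cav
  mito <- detectMitochondria(withCavity, NULL, vs, closingRadius = 1000)
  # the cavity comes back as one candidate (morphological-closing oracle:
  # the closed shape is the solid tube, so candidate ~= cavity)
  cavIdx <- which(cav & solid)
  allCand <- unlist(mito)
  expect_gt(mean(cavIdx %in% allCand), 0.98)
  expect_lt(length(setdiff(allCand, cavIdx)), 0.1 * length(cavIdx))
})

test_that("a cavity wider than the closing radius stays open", {
  vs <- c(25, 25, 50)
  shape <- c(220L, 220L, 110L)
  ctr <- (shape - 1) * vs / 2
  solid <- polylineTubeMask(rbind(c(ctr[1], ctr[2], 300),
                                  c(ctr[1], ctr[2], 5200)), 2600, shape, vs)
  co <- axomorph:::.gridCoordinates(shape, vs)
  cav <- sqrt((co$Y - ctr[1])^2 + (co$X - ctr[2])^2 + (co$Z - 2750)^2) <= 2000
  mito <- detectMitochondria(solid & !cav, NULL, vs, closingRadius = 1000,
                             minParent = 1e3)
  # 2 um cavity does not close under a 1 um radius
  expect_lt(length(unlist(mito)), 0.2 * sum(cav & solid))
})

test_that("the vacuole rule needs both small size and high brightness", {
  d <- c(40L, 40L, 30L)
  lab <- array(0L, d)
  lab[1:10, 1:10, 1:10] <- 1L       # 1000 voxels
  lab[11:40, 11:40, 1:30] <- 2L     # 27000 voxels
  lab[1:10, 21:30, 1:10] <- 3L      # 1000 voxels, dim
  z <- array(0.3, d)
  z[lab == 1L] <- 0.90
  z[lab == 2L] <- 0.90
  z[lab == 3L] <- 0.50
  seg <- AxonSegmentation(lab, c(15, 15, 50))
  vol <- SBEMVolume(z, c(15, 15, 50))
  out <- classifyVacuoles(seg, vol)
  tab <- segmentTable(out)
  expect_identical(tab$klass[tab$id == 1L], "VACUOLE")
  expect_identical(tab$klass[tab$id == 2L], "UNCLASSIFIED")  # too big
  expect_identical(tab$klass[tab$id == 3L], "UNCLASSIFIED")  # too dim
})

test_that("axon classification thresholds the enclosing myelin fraction", {
  # axon bar surrounded by a one-voxel shell; shell supervoxels carry a
  # controllable myelin fraction
  d <- c(13L, 13L, 6L)
  lab <- array(0L, d)
  lab[5:9, 5:9, 2:5] <- 1L        # 5 x 5 x 4 block: shell of 130 voxels
  seg0 <- AxonSegmentation(lab, c(15, 15, 50))
  shell <- axomorph:::.dilate6(lab == 1L) & lab != 1L
  svl <- array(3L, d)               # far field
  svl[lab == 1L] <- 1L
  svl[shell] <- 2L
  sv <- structure(list(labels = svl, Q = 3L, params = list()),
                  class = "SupervoxelPartition")
  mkMy <- function(frac) {
    my <- array(FALSE, d)
    idx <- which(shell)
    my[idx[seq_len(round(frac * length(idx)))]] <- TRUE
    my
  }
  cls <- function(frac) {
    segmentTable(classifyAxons(seg0, sv, mkMy(frac)))$klass[1L]
  }
  expect_identical(cls(0.9), "MYELINATED_AXON")
  expect_identical(cls(0.5), "UNMYELINATED_AXON")
  expect_identical(cls(0.7), "MYELINATED_AXON")   # >= threshold, inclusive
  # borderline call carries a review flag
  out <- classifyAxons(seg0, sv, mkMy(0.7))
  expect_true(segmentTable(out)$review_flag[1L])
})

test_that("cells are 26-connected components of the unlabelled leftovers", {
  d <- c(20L, 20L, 6L)
  expect_identical(attr(labelCells(array(FALSE, d)), "n"), 0L)
  un <- array(FALSE, d)
  un[2:6, 2:6, 2:4] <- TRUE
  un[12:18, 12:18, 2:5] <- TRUE
  cells <- labelCells(un)
  expect_identical(attr(cells, "n"), 2L)
  small <- labelCells(un, minSize = 100L)
  expect_identical(attr(small, "n"), 1L)
})

test_that("myelin redefinition subtracts mitochondria exactly", {
  d <- c(10L, 10L, 10L)
  V1 <- array(FALSE, d)
  V1[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  mito <- list(which(V1)[101:150])
  MY <- redefineMyelin(V1, mito)
  expect_identical(sum(MY), 950L)
  expect_identical(redefineMyelin(V1, list()), V1)
  expect_false(any(MY[mito[[1L]]]))
})
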