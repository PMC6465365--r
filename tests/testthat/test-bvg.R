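test_that("growth claims an intensity-separated block exactly", {
  z <- array(0.9, c(7, 7, 7))
  z[3:5, 3:5, 3:5] <- 0.20
  vol <- SBEMVolume(z, c(15, 15, 50))
  reg <- bvgGrow(vol, c(4, 4, 4), deltaT = 0.1)
  expect_setequal(as.integer(reg), which(z == 0.20))
  expect_false(attr(reg, "discarded"))

  # a neighbour at 0.35 stays out: |0.35 - 0.20| > 0.1
  z[2, 3, 3] <- 0.35
  vol <- SBEMVolume(z, c(15, 15, 50))
  reg <- bvgGrow(vol, c(4, 4, 4), deltaT = 0.1)
  expect_false(which(z == 0.35) %in% reg)
  expect_setequal(as.integer(reg), which(z == 0.20))
})

test_that("growth equals the brute-force batch oracle on ramp volumes", {
  set.seed(42)
  for (rep in 1:5) {
    d <- c(6L, 7L, 5L)
    base <- (seq_len(prod(d)) - 1) / prod(d)        # linear ramp
    z <- array(base + runif(prod(d), 0, 0.05), d)
    z <- (z - min(z)) / (max(z) - min(z))
    forb <- array(runif(prod(d)) < 0.1, d)
    seedCand <- which(!forb)
    s <- sample(seedCand, 1L)
    for (conn in c(6L, 26L)) {
      vol <- SBEMVolume(z, c(15, 15, 50))
      got <- bvgGrow(vol, s, forbidden = forb, deltaT = 0.15,
                     connectivity = conn)
      want <- bvgOracle(z, s, forb, deltaT = 0.15, connectivity = conn)
      expect_identical(sort(as.integer(got)), want$region)
    }
  }
})

test_that("the volume cap discards a region and frees its voxels", {
  z <- array(0.9, c(10, 10, 10))
  z[2:9, 2:9, 2:9] <- 0.2
  vol <- SBEMVolume(z, c(15, 15, 50))
  reg <- bvgGrow(vol, c(5, 5, 5), deltaT = 0.1, theta = 10)
  expect_true(attr(reg, "discarded"))
  oracle <- bvgOracle(z, axomorph:::.ijkToInd(c(5, 5, 5), dim(z)),
                      array(FALSE, dim(z)), 0.1, theta = 10)
  expect_true(oracle$discarded)
})

test_that("myelin growing stays within the seeded dark component", {
  z <- array(0.9, c(12, 12, 4))
  z[2:5, 2:5, ] <- 0.2          # structure A
  z[8:11, 8:11, ] <- 0.25       # structure B, disjoint
  vol <- SBEMVolume(z, c(15, 15, 50))
  edges <- list(raw = array(FALSE, dim(z)), dilated = array(FALSE, dim(z)))
  V1 <- segmentMyelin(vol, edges, seed = 1L)
  # exactly one of the two dark structures, never both
  inA <- sum(V1[2:5, 2:5, ]) > 0
  inB <- sum(V1[8:11, 8:11, ]) > 0
  expect_true(xor(inA, inB))
  expect_identical(sum(V1), 64L)

  bright <- SBEMVolume(array(0.9, c(6, 6, 2)), c(15, 15, 50))
  expect_error(segmentMyelin(bright, edges = list(dilated = array(FALSE, c(6, 6, 2)))),
               "seed")
})

test_that("seed extraction finds distance-transform maxima per slice", {
  d <- c(40L, 40L, 3L)
  B <- array(TRUE, d)
  # slice 1: one open disk -> one seed at its centre
  Y <- matrix(seq_len(40), 40, 40)
  X <- t(Y)
  disk <- (Y - 20.2)^2 + (X - 24.2)^2 <= 81
  B[, , 1L][disk] <- FALSE
  # slice 2: two disjoint open disks
  d1 <- (Y - 12)^2 + (X - 12)^2 <= 36
  d2 <- (Y - 30)^2 + (X - 28)^2 <= 49
  B[, , 2L][d1 | d2] <- FALSE
  # slice 3 entirely boundary: contributes nothing
  seeds <- extractSeeds(B, c(15, 15, 50))
  s1 <- seeds[seeds$z == 1L, ]
  expect_identical(nrow(s1), 1L)
  expect_lt((s1$y - 20.2)^2 + (s1$x - 24.2)^2, 2.1)
  s2 <- seeds[seeds$z == 2L, ]
  expect_true(any(d1[cbind(s2$y, s2$x)]))
  expect_true(any(d2[cbind(s2$y, s2$x)]))
  expect_identical(nrow(seeds[seeds$z == 3L, ]), 0L)
  # no seed lies in the boundary mask
  expect_false(any(B[cbind(seeds$y, seeds$x, seeds$z)]))
})

test_that("serial segmentation skips claimed seeds and is duplicate-proof", {
  z <- array(0.9, c(12, 12, 4))
  z[2:5, 2:5, ] <- 0.2
  z[8:11, 8:11, ] <- 0.6
  vol <- SBEMVolume(z, c(15, 15, 50))
  B <- array(FALSE, dim(z))
  seeds <- data.frame(y = c(3L, 4L, 9L), x = c(3L, 3L, 9L),
                      z = c(1L, 1L, 2L), slice = c(1L, 1L, 2L))
  seg <- segmentVolume(vol, B, seeds, deltaT = 0.1, theta = 1e6)
  tab <- segmentTable(seg)
  expect_identical(nrow(tab), 2L)      # duplicate seed in region 1 skipped
  segDup <- segmentVolume(vol, B, rbind(seeds, seeds), deltaT = 0.1,
                          theta = 1e6)
  expect_identical(labelData(segDup), labelData(seg))
  # regions disjoint from the boundary mask and from each other
  lab <- labelData(seg)
  expect_identical(sum(lab == 1L), 64L)
  expect_identical(sum(lab == 2L), 64L)
})
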