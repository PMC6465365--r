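test_that("phantom generation is deterministic and truth-consistent", {
  spec <- smallPhantomSpec(noiseSigma = 0.08, seed = 7L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(volData(a$volume), volData(b$volume))
  expect_identical(labelData(a$truth), labelData(b$truth))

  # class counts follow the spec
  tab <- segmentTable(a$truth)
  expect_identical(sum(tab$klass == "MYELINATED_AXON"), 2L)
  expect_identical(sum(tab$klass == "UNMYELINATED_AXON"), 0L)
  expect_identical(sum(tab$klass == "MYELIN"), 1L)

  # masking the noisy volume by a truth class recovers its mean
  z <- volData(a$volume)
  lab <- labelData(a$truth)
  m <- spec$intensityMeans
  expect_equal(mean(z[lab == 1L]), m[["myelin"]], tolerance = 0.01)
  axId <- tab$id[tab$klass == "MYELINATED_AXON"][1L]
  expect_equal(mean(z[lab == axId]), m[["axoplasm"]], tolerance = 0.01)
})

test_that("default phantom has the stated composition and connected myelin", {
  ph <- generatePhantom(phantomSpec(noiseSigma = 0))
  tab <- segmentTable(ph$truth)
  expect_identical(sum(tab$klass == "MYELINATED_AXON"), 4L)
  expect_identical(sum(tab$klass == "UNMYELINATED_AXON"), 2L)
  expect_identical(sum(tab$klass == "MITOCHONDRION"), 2L)
  expect_identical(sum(tab$klass == "VACUOLE"), 2L)
  expect_identical(sum(tab$klass == "CELL"), 1L)
  # mitochondria reference axon segments
  mito <- tab[tab$klass == "MITOCHONDRION", ]
  expect_true(all(mito$parent_axon_id %in%
                    tab$id[tab$klass == "MYELINATED_AXON"]))
  # myelin is a single connected structure
  my <- labelData(ph$truth) == 1L
  expect_identical(max(connectedComponents(my, 26L)), 1L)
  # sigma = 0: every voxel equals its class mean exactly
  z <- volData(ph$volume)
  lab <- labelData(ph$truth)
  expect_true(all(z[lab == 1L] == phantomSpec()$intensityMeans[["myelin"]]))
})

test_that("lumen overlap in the spec is rejected", {
  spec <- smallPhantomSpec()
  spec$axons[[2L]]$center <- spec$axons[[1L]]$center + c(30, 30)
  expect_error(generatePhantom(spec), "overlap")
})

test_that("analytic cylinder geometry matches closed forms", {
  expect_error(analyticCylinder(250, 90, 5000), "90")

  c0 <- analyticCylinder(radius = 300, tilt = 0, length = 4000,
                         shape = c(60L, 60L, 120L))
  expect_equal(c0$inPlaneMajor, c0$inPlaneMinor)

  c60 <- analyticCylinder(radius = 250, tilt = 60, length = 3000,
                          shape = c(40L, 220L, 70L), voxelSize = c(30, 30, 50))
  expect_equal(c60$inPlaneMajor, 1000, tolerance = 1e-12)

  # voxelized volume within 5% of pi r^2 L (continuous-cylinder oracle)
  vol <- sum(c0$mask) * prod(c(15, 15, 50))
  expect_equal(vol, pi * 300^2 * 4000, tolerance = 0.05)
  vol60 <- sum(c60$mask) * prod(c(30, 30, 50))
  expect_equal(vol60, pi * 250^2 * 3000, tolerance = 0.05)
})

test_that("polyline tubes have unbiased radii", {
  vs <- c(20, 20, 50)
  shape <- c(50L, 50L, 120L)
  ctr <- (shape - 1) * vs / 2
  m <- polylineTubeMask(rbind(c(ctr[1], ctr[2], 500),
                              c(ctr[1], ctr[2], 5500)), 300, shape, vs)
  # capsule volume: cylinder + sphere
  expect_equal(sum(m) * prod(vs), pi * 300^2 * 5000 + 4 / 3 * pi * 300^3,
               tolerance = 0.05)
})
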