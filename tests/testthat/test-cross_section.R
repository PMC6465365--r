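test_that("moment-matched ellipse recovers circle and ellipse closed forms", {
  # continuous circle, radius r: mu20 = mu02 = r^2/4
  m <- ellipseFromMoments(400^2 / 4, 400^2 / 4, 0, pi * 400^2)
  expect_equal(m$minor_axis, 800)
  expect_equal(m$major_axis, 800)
  expect_identical(m$eccentricity, 0)
  expect_equal(m$equivalent_diameter, 800)

  # continuous ellipse semi-axes (a, b): mu20 = a^2/4, mu02 = b^2/4
  a <- 1000; b <- 500
  m <- ellipseFromMoments(a^2 / 4, b^2 / 4, 0, pi * a * b)
  expect_equal(m$major_axis, 2 * a)
  expect_equal(m$minor_axis, 2 * b)
  expect_equal(m$eccentricity, sqrt(1 - 0.25))
  expect_equal(m$equivalent_diameter, 2 * sqrt(a * b))
})

test_that("rasterized ellipse measures are rotation invariant", {
  m0 <- measureBinarySection(rasterEllipse(1000, 500, 0, cell = 20, n = 161),
                             c(20, 20))
  m37 <- measureBinarySection(rasterEllipse(1000, 500, 37 * pi / 180,
                                            cell = 20, n = 161), c(20, 20))
  for (col in c("minor_axis", "major_axis", "eccentricity",
                "equivalent_diameter"))
    expect_equal(m37[[col]], m0[[col]], tolerance = 0.01)
  expect_equal(m0$major_axis, 2000, tolerance = 0.01)
  expect_equal(m0$minor_axis, 1000, tolerance = 0.01)
})

test_that("perpendicular sections of a z cylinder are circular disks", {
  vs <- c(15, 15, 50)
  cyl <- analyticCylinder(radius = 500, tilt = 0, length = 1e9,
                          shape = c(80L, 80L, 60L), voxelSize = vs)
  pt <- c(cyl$center[1], cyl$center[2], 1500)
  cs <- sampleCrossSection(cyl$mask, vs, pt, c(0, 0, 1))
  m <- measureCrossSection(cs)
  expect_equal(m$equivalent_diameter, 1000, tolerance = 0.01)
  expect_lt(m$eccentricity, 0.1)
  # oblique sampling at 60 degrees doubles the area
  cs2 <- sampleCrossSection(cyl$mask, vs, pt, c(0, sin(pi / 3), cos(pi / 3)))
  m2 <- measureCrossSection(cs2)
  expect_equal(m2$area / (pi * 500^2), 2, tolerance = 0.03)
})

test_that("an empty or sliver section is flagged", {
  vs <- c(15, 15, 50)
  mask <- array(FALSE, c(30, 30, 10))
  cs <- sampleCrossSection(mask, vs, c(200, 200, 250), c(0, 0, 1))
  expect_true(cs$empty)
  expect_null(measureCrossSection(cs))
})

test_that("morphometry recovers cylinder diameter and honours the filter", {
  vs <- c(15, 15, 50)
  mask <- capsuleMask(radius = 400, tipLength = 10000,
                      shape = c(64L, 64L, 232L), voxelSize = vs)
  sk <- extractSkeleton(mask, vs, axonId = 1L)
  am <- axonMorphometry(mask, sk, vs, every = 4L)
  expect_equal(unname(am$medians["equivalent_diameter"]), 800,
               tolerance = 0.1)
  expect_lte(unname(am$medians["eccentricity"]), 0.3)
  expect_true(am$included)                    # ~8 um >= 5 um
  # medians lie inside the range of their series
  for (col in c("minor_axis", "major_axis", "equivalent_diameter"))
    expect_true(am$medians[col] >= min(am$series[[col]]) &&
                am$medians[col] <= max(am$series[[col]]))
  # a 4 um tube fails the 5 um filter
  short <- capsuleMask(radius = 400, tipLength = 4000,
                       shape = c(64L, 64L, 100L), voxelSize = vs)
  sk2 <- extractSkeleton(short, vs, axonId = 2L)
  am2 <- axonMorphometry(short, sk2, vs, every = 4L)
  expect_false(am2$included)
})

test_that("varying radius profiles land between their bounds", {
  # sinusoidal radius r in [300, 500] nm along z
  vs <- c(15, 15, 50)
  d <- c(90L, 90L, 200L)
  ny <- d[1L]
  cy <- (ny - 1) * 15 / 2
  Y <- matrix((seq_len(ny) - 1) * 15, ny, ny)
  X <- t(Y)
  mask <- array(FALSE, d)
  for (k in seq_len(d[3L])) {
    r <- 400 + 100 * sin(2 * pi * (k - 1) * 50 / 3000)
    mask[, , k] <- (Y - cy)^2 + (X - cy)^2 <= r^2
  }
  sk <- extractSkeleton(mask, vs, axonId = 3L)
  am <- axonMorphometry(mask, sk, vs, every = 4L)
  eqd <- am$series$equivalent_diameter
  expect_true(all(eqd > 2 * 300 * 0.9 & eqd < 2 * 500 * 1.1))
  med <- unname(am$medians["equivalent_diameter"])
  expect_gt(med, min(eqd))
  expect_lt(med, max(eqd))
})

test_that("tangent estimation is accurate on straight skeletons", {
  vs <- c(15, 15, 50)
  mask <- capsuleMask(radius = 300, tipLength = 8000,
                      shape = c(48L, 48L, 180L), voxelSize = vs)
  sk <- extractSkeleton(mask, vs, axonId = 1L)
  tg <- skeletonTangents(sk)
  ang <- acos(pmin(abs(tg[, 3]), 1)) * 180 / pi
  expect_lt(mean(ang), 3)
})
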