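test_that("relative difference is symmetric, scale-invariant and bounded", {
  expect_equal(relativeDifference(3, 3), 0)
  expect_equal(relativeDifference(2, 1), 0.5)
  expect_equal(relativeDifference(1, 2), 0.5)
  expect_true(is.nan(relativeDifference(0, 0)))
  set.seed(1)
  q1 <- runif(50); q2 <- runif(50)
  expect_equal(relativeDifference(q1, q2), relativeDifference(q2, q1))
  expect_equal(relativeDifference(10 * q1, 10 * q2),
               relativeDifference(q1, q2))
  expect_true(all(relativeDifference(q1, q2) >= 0 &
                  relativeDifference(q1, q2) <= 1))
  expect_error(relativeDifference(-1, 2), "nonnegative")
})

test_that("nested ANOVA matches the projection-matrix oracle on unbalanced data", {
  set.seed(9)
  # 2 groups, animals with 2/3/2 axons
  df <- data.frame(
    group = c(rep("sham", 5), rep("tbi", 4)),
    animal = c("a1", "a1", "a2", "a2", "a2", "b1", "b1", "b2", "b2"),
    value = rnorm(9, mean = c(rep(0, 5), rep(1, 4))))
  got <- nestedAnova(df)
  want <- nestedAnovaOracle(df)
  expect_equal(got$table$ss[1], want$ssG, tolerance = 1e-8)
  expect_equal(got$table$ss[2], want$ssA, tolerance = 1e-8)
  expect_equal(got$table$ss[3], want$ssE, tolerance = 1e-8)
  expect_equal(got$F, want$F, tolerance = 1e-8)
  expect_equal(got$p, want$p, tolerance = 1e-8)
})

test_that("nested ANOVA reduces to one-way ANOVA with one axon per animal", {
  set.seed(4)
  df <- data.frame(group = rep(c("g1", "g2", "g3"), each = 6),
                   animal = paste0("an", 1:18),
                   value = rnorm(18, rep(c(0, 0.5, 1), each = 6)))
  got <- nestedAnova(df)
  # textbook one-way oracle: between-group MS over within-group MS
  fit <- stats::aov(value ~ group, df)
  sm <- summary(fit)[[1]]
  expect_equal(got$F, sm[["F value"]][1], tolerance = 1e-10)
  expect_equal(got$p, sm[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("degenerate responses yield NaN statistics", {
  df <- data.frame(group = rep(c("a", "b"), each = 4),
                   animal = rep(c("a1", "a2", "b1", "b2"), each = 2),
                   value = 1)
  out <- nestedAnova(df)
  expect_true(is.nan(out$F))
  expect_true(is.nan(out$p))
})

test_that("a strong group effect is detected reliably", {
  # group means five animal-SDs apart, small axon-level noise
  hits <- 0L
  for (s in 1:40) {
    df <- nestedData(nGroups = 2, nAnimals = 4, nAxons = 8, nCross = 1,
                     sdAnimal = 0.2, sdAxon = 0.1, sdCross = 1e-6,
                     groupShift = 1.0, seed = s)
    agg <- stats::aggregate(value ~ group + animal + axon, df, stats::median)
    out <- nestedAnova(agg)
    if (out$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("variance components recover the generating partition", {
  # only within-axon noise: cross-section level takes nearly everything
  df <- nestedData(nGroups = 1, nAnimals = 4, nAxons = 10, nCross = 30,
                   sdAnimal = 1e-6, sdAxon = 1e-6, sdCross = 1, seed = 2)
  vc <- varianceComponents(df, subsampleN = nrow(df), repeats = 1)
  expect_gte(vc$mean[["cross_section"]], 95)

  # known 60/35/5 percent split
  df <- nestedData(nGroups = 1, nAnimals = 6, nAxons = 45, nCross = 40,
                   sdAnimal = sqrt(5), sdAxon = sqrt(35), sdCross = sqrt(60),
                   seed = 3)
  vc <- varianceComponents(df, subsampleN = 10000, repeats = 5, seed = 1)
  expect_lt(abs(vc$mean[["cross_section"]] - 60), 5)
  expect_lt(abs(vc$mean[["axon"]] - 35), 5)
  expect_lt(abs(vc$mean[["animal"]] - 5), 5)
  expect_true(all(vc$percent >= 0))
  expect_true(all(abs(rowSums(vc$percent) - 100) < 1e-6))

  # zero variance everywhere: all-zero components with a warning-free pass
  df0 <- data.frame(animal = rep(c("a", "b"), each = 8),
                    axon = rep(c("x1", "x2", "y1", "y2"), each = 4),
                    value = 2)
  vc0 <- varianceComponents(df0, subsampleN = 16, repeats = 1)
  expect_true(all(vc0$mean == 0))
})

test_that("subsampling beyond the dataset size falls back to the full data", {
  df <- nestedData(nGroups = 1, nAnimals = 2, nAxons = 3, nCross = 5, seed = 6)
  expect_warning(vc <- varianceComponents(df, subsampleN = 1e5, repeats = 10),
                 "full data")
  expect_identical(nrow(vc$percent), 1L)
})

test_that("2D simulation picks the plane family by elongation", {
  vs <- c(15, 15, 50)
  mask <- analyticCylinder(radius = 300, tilt = 0, length = 1e9,
                           shape = c(48L, 48L, 120L), voxelSize = vs)$mask
  m <- simulate2dMeasure(mask, vs, seed = 2L)
  expect_identical(m$family, "x-y")       # z-elongated -> x-y sections
  expect_equal(m$minor_axis, 600, tolerance = 0.05)
  # a sphere: any family; the random section never exceeds the equator
  co <- axomorph:::.gridCoordinates(c(60L, 60L, 24L), c(15, 15, 50))
  ball <- sqrt((co$Y - 442.5)^2 + (co$X - 442.5)^2 + (co$Z - 575)^2) <= 400
  ms <- simulate2dMeasure(ball, c(15, 15, 50), seed = 4L)
  expect_lte(ms$equivalent_diameter, 2 * 400 * 1.03)
})

test_that("volumetrics reproduce the closed-form aggregate g-ratio", {
  d <- c(20L, 20L, 10L)
  lab <- array(0L, d)
  lab[1:10, , ] <- 1L                      # myelin: 2000 voxels
  lab[11:19, 1:10, ] <- 2L                 # myelinated axon
  tab <- data.frame(id = 1:2, klass = c("MYELIN", "MYELINATED_AXON"),
                    voxel_count = c(sum(lab == 1L), sum(lab == 2L)),
                    parent_axon_id = NA_integer_, review_flag = FALSE)
  seg <- AxonSegmentation(lab, c(15, 15, 50), tab)
  v <- volumetrics(seg)
  myelinStar <- sum(lab == 1L) / (sum(lab == 1L) + sum(lab == 2L))
  expect_equal(v$myelin_star, myelinStar)
  expect_equal(v$aggregate_g_ratio, sqrt(1 - myelinStar))
  # Myelin* = 0.36 -> g = 0.8 (closed form through the same code path)
  tab2 <- tab
  tab2$voxel_count <- c(36L, 64L)
  lab2 <- array(0L, c(10L, 10L, 1L))
  lab2[1:36] <- 1L
  lab2[37:100] <- 2L
  seg2 <- AxonSegmentation(lab2, c(15, 15, 50), tab2)
  v2 <- volumetrics(seg2)
  expect_equal(v2$aggregate_g_ratio, 0.8)
  # each myelinated axon counted once in the density
  expect_equal(v2$density_myelinated_axons * v2$noncellular_volume_um3, 1)
})
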