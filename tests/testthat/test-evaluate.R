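test_that("precision and recall follow their definitions", {
  d <- c(10L, 10L, 2L)
  A <- array(FALSE, d); B <- array(FALSE, d)
  A[1:10, 1, 1] <- TRUE
  B[1:8, 1, 1] <- TRUE; B[1:2, 2, 1] <- TRUE
  pr <- precisionRecall(A, B)
  expect_equal(unname(pr["precision"]), 0.8)
  expect_equal(unname(pr["recall"]), 0.8)
  expect_equal(unname(precisionRecall(A, A)), c(1, 1))
  expect_warning(pr0 <- precisionRecall(A, array(FALSE, d)), "empty")
  expect_true(is.nan(pr0[["precision"]]))
  expect_identical(pr0[["recall"]], 0)
  expect_error(precisionRecall(A, array(FALSE, c(2, 2, 2))), "shape")
})

test_that("identical and disjoint partitions hit the metric extremes", {
  d <- c(12L, 12L, 3L)
  lab <- array(0L, d)
  lab[1:5, 1:5, ] <- 1L
  lab[7:12, 7:12, ] <- 2L
  same <- weightedRegionOverlap(lab, lab)
  expect_equal(same$weighted_jaccard, 1)
  expect_equal(same$weighted_dice, 1)
  other <- array(0L, d)
  other[6, 6, ] <- 9L
  disj <- weightedRegionOverlap(lab, other)
  expect_equal(disj$weighted_jaccard, 0)
  expect_equal(disj$weighted_dice, 0)
})

test_that("optimal matching equals exhaustive permutation search", {
  set.seed(11)
  for (rep in 1:8) {
    a <- sample(2:4, 1L); b <- sample(2:4, 1L)
    d <- c(30L, 30L, 1L)
    ref <- array(0L, d); pred <- array(0L, d)
    # random blobby regions
    for (i in seq_len(a)) ref[sample.int(900, 60) ] <- i
    for (j in seq_len(b)) pred[sample.int(900, 60)] <- j
    got <- weightedRegionOverlap(ref, pred)
    refIds <- sort(unique(ref[ref > 0]))
    predIds <- sort(unique(pred[pred > 0]))
    diceMat <- outer(refIds, predIds, Vectorize(function(i, j)
      diceCoef(ref == i, pred == j)))
    oracle <- assignmentOracle(diceMat)
    expect_equal(sum(got$matching$dice), oracle$total, tolerance = 1e-12)
    # weighted metrics from the oracle assignment
    w <- tabulate(ref[ref > 0])[refIds]
    w <- w / sum(w)
    oDice <- 0
    for (i in seq_along(refIds)) {
      j <- oracle$assignment[i]
      if (j <= length(predIds)) oDice <- oDice + w[i] * diceMat[i, j]
    }
    expect_equal(got$weighted_dice, oDice, tolerance = 1e-12)
    # Dice >= Jaccard always
    expect_gte(got$weighted_dice, got$weighted_jaccard)
  }
})

test_that("splitting a matched region strictly lowers the weighted Dice", {
  d <- c(20L, 20L, 2L)
  ref <- array(0L, d)
  ref[1:10, 1:20, ] <- 1L
  whole <- ref
  split <- ref
  split[1:10, 11:20, ] <- 2L
  before <- weightedRegionOverlap(ref, whole)$weighted_dice
  after <- weightedRegionOverlap(ref, split)$weighted_dice
  expect_lt(after, before)
  expect_equal(before, 1)
})

test_that("metrics are invariant to region id relabelling", {
  d <- c(15L, 15L, 2L)
  set.seed(2)
  ref <- array(sample(0:3, prod(d), replace = TRUE), d)
  pred <- array(sample(0:3, prod(d), replace = TRUE), d)
  relab <- pred
  relab[pred == 1L] <- 7L
  relab[pred == 2L] <- 5L
  relab[pred == 3L] <- 9L
  a <- weightedRegionOverlap(ref, pred)
  b <- weightedRegionOverlap(ref, relab)
  expect_equal(a$weighted_dice, b$weighted_dice)
  expect_equal(a$weighted_jaccard, b$weighted_jaccard)
})

test_that("segmentation reports work on whole volumes and slice subsets", {
  ph <- generatePhantom(smallPhantomSpec())
  ev3 <- evaluateSegmentation(ph$truth, ph$truth)
  expect_identical(ev3$mode, "3d")
  expect_equal(ev3$classes$MYELIN$weighted_dice, 1)
  expect_equal(ev3$classes$MYELINATED_AXON$weighted_dice, 1)
  ev2 <- evaluateSegmentation(ph$truth, ph$truth, slices = c(10L, 20L, 30L))
  expect_identical(ev2$mode, "2d-slices")
  expect_equal(ev2$classes$MYELINATED_AXON$precision, 1)
})
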