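# Analysis layer: 2D-vs-3D comparison, nested ANOVA with an
# expected-mean-squares F test, variance components, and volumetric
# summaries.

#' Simulate a 2D morphometric measurement of an axon
#'
#' Mimics single-section morphometry: an ellipsoid is fitted to the axon
#' voxel cloud (second moments in physical coordinates); the image-plane
#' family most orthogonal to the principal elongation axis is chosen among
#' {x-y, x-z, y-z}; one plane intersecting the axon is drawn at random; and
#' that native 2D section is measured with the same moment machinery as the
#' 3D cross-sections.
#'
#' @param mask logical 3D axon mask.
#' @param voxelSize numeric(3) nm.
#' @param seed RNG seed for the slice draw.
#' @param family NULL for the automatic ellipsoid-orientation choice, or one
#'   of "x-y", "x-z", "y-z" to force the sectioning plane family (e.g. to
#'   quantify the bias of sectioning a tilted axon in the native image
#'   plane).
#' @return one-row data.frame of section measures plus \code{family} and
#'   \code{sliceIndex}.
#' @export
simulate2dMeasure <- function(mask, voxelSize, seed = 1L, family = NULL) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty axon mask")
  P <- sweep(w - 1, 2, voxelSize, "*")
  cv <- stats::cov(P)
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 1L]                 # principal elongation, (y, x, z)
  normalAxis <- if (is.null(family)) which.max(abs(axis))
                else match(family, c("x-z", "y-z", "x-y"))
  # family: planes perpendicular to that array axis
  idx <- sort(unique(w[, normalAxis]))
  k <- withSeed(seed, sample(idx, 1L))
  sl <- switch(normalAxis,
               mask[k, , , drop = TRUE],   # y-normal: (x, z) plane
               mask[, k, , drop = TRUE],   # x-normal: (y, z) plane
               mask[, , k, drop = TRUE])   # z-normal: (y, x) plane
  cell <- switch(normalAxis,
                 voxelSize[c(2L, 3L)],
                 voxelSize[c(1L, 3L)],
                 voxelSize[c(1L, 2L)])
  # keep only the component at the slice's centroid of the axon to mirror
  # measuring a single profile
  lab <- connectedComponents(array(sl, c(dim(sl), 1L)), 26L)[, , 1L]
  if (max(lab) > 1L) {
    sz <- tabulate(lab[lab > 0L])
    sl <- lab == which.max(sz)
  }
  m <- measureBinarySection(sl, cell)
  m$family <- c("x-z", "y-z", "x-y")[normalAxis]
  m$sliceIndex <- k
  m
}

#' Relative difference between 2D and 3D quantifications
#'
#' |q2d - q3d| / max(q2d, q3d): symmetric, scale-invariant, in [0, 1] for
#' nonnegative inputs; NaN if both are zero.
#'
#' @param q2d,q3d nonnegative measurement values (vectorized).
#' @return relative difference(s).
#' @export
relativeDifference <- function(q2d, q3d) {
  if (any(q2d < 0 | q3d < 0, na.rm = TRUE))
    stop("quantities must be nonnegative")
  mx <- pmax(q2d, q3d)
  ifelse(mx == 0, NaN, abs(q2d - q3d) / mx)
}

#' Nested one-way ANOVA (group with animals nested in group)
#'
#' Sums of squares by sequential model comparison (equivalent to type II for
#' this fully nested design): group, animal-within-group, residual. Animals
#' are a random factor, so the group effect is tested against the
#' animal-within-group mean square: F = MS(group) / MS(animal in group).
#' The response should be one value per axon (the median of its
#' cross-sectional measurements).
#'
#' @param data data.frame with columns \code{group}, \code{animal},
#'   \code{value}; animals must be nested (each animal in one group).
#' @param response name of the response column (default "value").
#' @return list of class \code{AnovaResult}: F, p, df, the SS/MS table.
#' @export
nestedAnova <- function(data, response = "value") {
  g <- factor(data$group)
  a <- factor(paste(data$group, data$animal, sep = "/"))
  y <- data[[response]]
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(rowSums(table(data$animal, g) > 0) > 1))
    stop("animals must be nested within groups")
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  rss1 <- rss(stats::model.matrix(~g))
  rss2 <- rss(stats::model.matrix(~a))
  ssG <- rss0 - rss1
  ssA <- rss1 - rss2
  ssE <- rss2
  dfG <- nlevels(g) - 1L
  dfA <- nlevels(a) - nlevels(g)
  dfE <- n - nlevels(a)
  msG <- ssG / dfG
  msA <- ssA / dfA
  msE <- if (dfE > 0) ssE / dfE else NA_real_
  Fg <- if (rss0 <= .Machine$double.eps * n || msA <= 0) NaN else msG / msA
  p <- if (is.nan(Fg)) NaN else stats::pf(Fg, dfG, dfA, lower.tail = FALSE)
  tab <- data.frame(term = c("group", "animal_in_group", "residual"),
                    df = c(dfG, dfA, dfE), ss = c(ssG, ssA, ssE),
                    ms = c(msG, msA, msE))
  structure(list(F = Fg, p = p, df = c(dfG, dfA), table = tab),
            class = "AnovaResult")
}

#' Variance components of nested cross-section measurements
#'
#' Method-of-moments (expected mean squares) partition of the variance of
#' cross-section-level measurements into cross-sectional, axonal, and animal
#' levels, on random subsamples: \code{subsampleN} measurements drawn
#' without replacement, repeated \code{repeats} times; the mean and SD over
#' repeats are reported. Negative moment estimates are truncated at zero
#' (the raw values are kept in the result) before converting to percent of
#' total.
#'
#' @param data data.frame with columns \code{animal}, \code{axon},
#'   \code{value} (one row per cross-section).
#' @param subsampleN subsample size (default 10000); if it exceeds the data
#'   size the full data is used once, with a warning.
#' @param repeats number of subsampling repeats (default 10).
#' @param seed RNG seed; repeat r uses seed + r.
#' @return list of class \code{VarianceComponents}: \code{percent} (matrix
#'   repeats x 3), \code{mean}, \code{sd}, \code{raw} (unt runcated variance
#'   estimates of the last repeat).
#' @export
varianceComponents <- function(data, subsampleN = 10000L, repeats = 10L,
                               seed = 1L) {
  N <- nrow(data)
  if (subsampleN >= N) {
    if (subsampleN > N)
      warning("subsample exceeds data size: using the full data once")
    subsampleN <- N
    repeats <- 1L
  }
  res <- matrix(NA_real_, repeats, 3L,
                dimnames = list(NULL, c("cross_section", "axon", "animal")))
  raw <- NULL
  for (r in seq_len(repeats)) {
    idx <- withSeed(seed + r, sample.int(N, subsampleN))
    est <- .nestedVarComp(data[idx, , drop = FALSE])
    raw <- est
    tot <- sum(pmax(est, 0))
    res[r, ] <- if (tot > 0) 100 * pmax(est, 0) / tot else c(0, 0, 0)
  }
  structure(list(percent = res, mean = colMeans(res),
                 sd = apply(res, 2L, stats::sd), raw = raw),
            class = "VarianceComponents")
}

# unbalanced two-level nested random-effects variance components
# (animal / axon-within-animal / residual) by expected mean squares
.nestedVarComp <- function(df) {
  an <- factor(df$animal)
  ax <- factor(paste(df$animal, df$axon, sep = "/"))
  y <- df$value
  N <- length(y)
  a <- nlevels(an)
  b <- nlevels(ax)
  if (b <= a || a < 2L) return(c(stats::var(y), 0, 0))

  nij <- as.numeric(table(ax))                    # per-axon counts
  axAnimal <- an[match(levels(ax), ax)]           # animal of each axon
  Ni <- as.numeric(tapply(nij, axAnimal, sum))    # per-animal counts

  mAx <- tapply(y, ax, mean)
  mAn <- tapply(y, an, mean)
  grand <- mean(y)

  ssW <- sum((y - mAx[ax])^2)
  ssAx <- sum(nij * (mAx - mAn[axAnimal])^2)
  ssAn <- sum(Ni * (mAn - grand)^2)

  dfW <- N - b
  dfAx <- b - a
  dfAn <- a - 1L

  msW <- ssW / dfW
  msAx <- ssAx / dfAx
  msAn <- ssAn / dfAn

  sumNij2perAnimal <- tapply(nij^2, axAnimal, sum)
  c1 <- (N - sum(sumNij2perAnimal / Ni)) / dfAx
  c2 <- (sum(sumNij2perAnimal / Ni) - sum(nij^2) / N) / dfAn
  c3 <- (N - sum(Ni^2) / N) / dfAn

  s2 <- msW
  s2ax <- (msAx - s2) / c1
  s2an <- (msAn - s2 - c2 * max(s2ax, 0)) / c3
  c(cross_section = s2, axon = s2ax, animal = s2an)
}

#' Volumetric summaries of an annotated segmentation
#'
#' Computes Myelin* (myelin volume over myelin plus intra-axonal volume of
#' myelinated axons, mitochondria included), the aggregate g-ratio
#' sqrt(1 - Myelin*) — a thickness-free implicit g-ratio — densities of
#' myelinated axons and mitochondria per um^3 of non-cellular volume (each
#' object counted once), and per-class volume fractions.
#'
#' @param seg a fully annotated \linkS4class{AxonSegmentation}.
#' @return list of class \code{Volumetrics}.
#' @export
volumetrics <- function(seg) {
  tab <- segmentTable(seg)
  vs <- voxelSize(seg)
  voxUm3 <- prod(vs) / 1e9
  total <- prod(dim(seg)) * voxUm3

  vol <- function(klass) sum(tab$voxel_count[tab$klass == klass]) * voxUm3
  myelin <- vol("MYELIN")
  myAxIds <- tab$id[tab$klass == "MYELINATED_AXON"]
  intraAxonal <- sum(tab$voxel_count[tab$id %in% myAxIds]) * voxUm3 +
    sum(tab$voxel_count[tab$klass == "MITOCHONDRION" &
                        tab$parent_axon_id %in% myAxIds]) * voxUm3
  if (intraAxonal + myelin <= 0) stop("no myelinated-axon volume to summarize")
  myelinStar <- myelin / (myelin + intraAxonal)
  vnc <- total - vol("CELL")
  nMyAx <- length(myAxIds)
  nMito <- sum(tab$klass == "MITOCHONDRION")

  fractions <- vapply(.SEGMENT_CLASSES,
                      function(k) vol(k) / total, numeric(1L))
  structure(list(myelin_star = myelinStar,
                 aggregate_g_ratio = sqrt(1 - myelinStar),
                 density_myelinated_axons = nMyAx / vnc,
                 density_mitochondria = nMito / vnc,
                 volume_fractions = fractions,
                 total_volume_um3 = total,
                 noncellular_volume_um3 = vnc),
            class = "Volumetrics")
}
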