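# Segmentation-accuracy metrics: tissue-level precision/recall and
# region-level weighted Jaccard/Dice with optimal one-to-one region matching.

#' Tissue-level precision and recall
#'
#' Precision = |A ∩ B| / |B|, Recall = |A ∩ B| / |A|, with A the reference
#' mask and B the prediction. An empty prediction yields NaN precision (with
#' a warning); an empty reference yields NaN recall.
#'
#' @param ref,pred logical arrays of one tissue type.
#' @return named numeric: precision, recall.
#' @export
precisionRecall <- function(ref, pred) {
  if (!identical(dim(ref), dim(pred))) stop("mask shapes differ")
  inter <- sum(ref & pred)
  nB <- sum(pred)
  nA <- sum(ref)
  if (nB == 0L) warning("empty prediction: precision undefined")
  if (nA == 0L) warning("empty reference: recall undefined")
  c(precision = if (nB > 0L) inter / nB else NaN,
    recall = if (nA > 0L) inter / nA else NaN)
}

# Hungarian algorithm (Jonker-style shortest augmenting paths with
# potentials), minimizing total cost of a square matrix. Returns the column
# assigned to each row. O(n^3).
.hungarian <- function(cost) {
  n <- nrow(cost)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                  # columns are offset by 1 (index 1 = virtual)
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n) + 1L) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign
}

#' Region-level weighted Jaccard and Dice with optimal matching
#'
#' Each reference region is matched one-to-one to at most one predicted
#' region by maximizing the total Dice coefficient over all assignments
#' (Hungarian algorithm on the pairwise Dice matrix; unequal counts are
#' handled by zero-Dice padding). The weighted metrics average the per-match
#' Jaccard/Dice with weights w_i proportional to reference-region size;
#' unmatched reference regions contribute zero. Region-level matching makes
#' the metrics very sensitive to split-and-merge errors.
#'
#' @param refLabels,predLabels integer arrays of region labels (0 =
#'   background); regions are the distinct nonzero labels.
#' @return list: \code{weighted_jaccard}, \code{weighted_dice},
#'   \code{matching} data.frame (ref, pred, dice, jaccard, weight; pred NA
#'   when unmatched).
#' @export
weightedRegionOverlap <- function(refLabels, predLabels) {
  if (!identical(dim(refLabels), dim(predLabels))) stop("shapes differ")
  refIds <- sort(unique(refLabels[refLabels > 0L]))
  if (length(refIds) == 0L) stop("reference contains no regions")
  predIds <- sort(unique(predLabels[predLabels > 0L]))

  refSize <- tabulate(refLabels[refLabels > 0L], nbins = max(refIds))[refIds]
  a <- length(refIds)
  b <- length(predIds)
  dice <- matrix(0, a, max(b, 1L))
  jac <- matrix(0, a, max(b, 1L))
  if (b > 0L) {
    predSize <- tabulate(predLabels[predLabels > 0L], nbins = max(predIds))[predIds]
    both <- refLabels > 0L & predLabels > 0L
    if (any(both)) {
      pairTab <- table(ref = factor(refLabels[both], levels = refIds),
                       pred = factor(predLabels[both], levels = predIds))
      inter <- matrix(as.numeric(pairTab), a, b)
      dice <- 2 * inter / outer(refSize, predSize, "+")
      jac <- inter / (outer(refSize, predSize, "+") - inter)
    }
  }

  n <- max(a, b)
  full <- matrix(0, n, n)
  full[seq_len(a), seq_len(ncol(dice))] <- dice
  assign <- .hungarian(1 - full)   # maximize total Dice

  w <- refSize / sum(refSize)
  match <- data.frame(ref = refIds, pred = NA_integer_, dice = 0,
                      jaccard = 0, weight = w)
  for (i in seq_len(a)) {
    j <- assign[i]
    if (j >= 1L && j <= b && dice[i, j] > 0) {
      match$pred[i] <- predIds[j]
      match$dice[i] <- dice[i, j]
      match$jaccard[i] <- jac[i, j]
    }
  }
  list(weighted_jaccard = sum(match$weight * match$jaccard),
       weighted_dice = sum(match$weight * match$dice),
       matching = match)
}

#' Evaluate a segmentation against a reference annotation
#'
#' Tissue-level precision/recall per class and region-level weighted metrics
#' where each axon is its own region. Evaluation can run on the full volume
#' or on selected z slices (the reference may be a sparse manual
#' annotation).
#'
#' @param ref,pred \linkS4class{AxonSegmentation} objects on the same grid.
#' @param classes tissue classes to evaluate.
#' @param slices optional integer z indices restricting the evaluation.
#' @return list of class \code{EvalReport}: per-class precision/recall,
#'   per-class region-level weighted metrics, and the evaluation mode.
#' @export
evaluateSegmentation <- function(ref, pred,
                                 classes = c("MYELIN", "MYELINATED_AXON",
                                             "UNMYELINATED_AXON"),
                                 slices = NULL) {
  refLab <- labelData(ref); predLab <- labelData(pred)
  if (!is.null(slices)) {
    refLab <- refLab[, , slices, drop = FALSE]
    predLab <- predLab[, , slices, drop = FALSE]
  }
  refTab <- segmentTable(ref); predTab <- segmentTable(pred)
  out <- list()
  for (cl in classes) {
    rids <- refTab$id[refTab$klass == cl]
    pids <- predTab$id[predTab$klass == cl]
    rmask <- array(refLab %in% rids, dim(refLab))
    pmask <- array(predLab %in% pids, dim(predLab))
    pr <- suppressWarnings(precisionRecall(rmask, pmask))
    rl <- array(ifelse(rmask, refLab, 0L), dim(refLab))
    pl <- array(ifelse(pmask, predLab, 0L), dim(predLab))
    region <- if (any(rmask))
      weightedRegionOverlap(rl, pl)
    else list(weighted_jaccard = NA_real_, weighted_dice = NA_real_,
              matching = NULL)
    out[[cl]] <- list(precision = unname(pr["precision"]),
                      recall = unname(pr["recall"]),
                      weighted_jaccard = region$weighted_jaccard,
                      weighted_dice = region$weighted_dice,
                      matching = region$matching)
  }
  structure(list(classes = out,
                 mode = if (is.null(slices)) "3d" else "2d-slices",
                 slices = slices),
            class = "EvalReport")
}
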