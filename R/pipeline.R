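# End-to-end orchestration: denoise -> edges -> myelin growing -> seeding ->
# serial growing -> supervoxel refinement -> annotation -> skeletons ->
# cross-section morphometry -> volumetrics, with optional per-stage
# checkpoints (TIFF/CSV) and a single RNG seed for full determinism.

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: similarity threshold
#' 0.1, volume cap 1e6 voxels, supervoxel compactness 23 and grid step 11,
#' refinement threshold 5e3 voxels, 1 um cavity closing, vacuole rule
#' (< 2e4 voxels, mean >= 0.85), myelin fraction 0.7, 25 nm skeleton step,
#' 8 um / 50 nm cross-section frame, 1 um end trimming, 5 um length filter.
#'
#' @param ... named overrides, e.g. \code{bvg = list(theta = 2e5)}; merged
#'   per stage over the defaults.
#' @return nested list of stage parameter blocks.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    denoise = list(method = "nlmeans", params = list()),
    canny = list(sd = sqrt(2), weak = 0.25, strong = 0.6, dilation = 3L,
                 mode = "slice"),
    bvg = list(deltaT = 0.1, theta = 1e6, myelinSeedMax = 0.4),
    slic = list(compactness = 23, step = 11),
    refine = list(minLarge = 5e3),
    annotate = list(closingNm = 1000, mitoMinParent = 1e4, vacuoleMax = 2e4,
                    vacuoleMean = 0.85, myelinFrac = 0.7, cellMin = 5e3),
    skeleton = list(stepNm = 25, trimNm = 1000, order = "msfm"),
    morphometry = list(lengthMinUm = 5, every = 1L),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Run the full segmentation and morphometry pipeline
#'
#' @param vol an \linkS4class{SBEMVolume}.
#' @param config from \code{\link{pipelineConfig}}.
#' @param checkpointDir optional directory for per-stage artifacts
#'   (TIFF/CSV).
#' @param morphometry run the skeleton/cross-section stage (default TRUE).
#' @param verbose print stage progress.
#' @return list with \code{segmentation} (annotated
#'   \linkS4class{AxonSegmentation}), \code{myelinMask}, \code{morphometry}
#'   (per-axon list), \code{summary} (per-axon data.frame),
#'   \code{volumetrics}, \code{config}.
#' @export
runPipeline <- function(vol, config = pipelineConfig(), checkpointDir = NULL,
                        morphometry = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  ck <- function(name, writer) {
    if (!is.null(checkpointDir)) {
      dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
      writer(file.path(checkpointDir, name))
    }
  }
  vs <- voxelSize(vol)

  say("denoising (%s)", config$denoise$method)
  den <- denoiseVolume(vol, config$denoise$method, config$denoise$params)
  ck("denoised.tif", function(p) writeVolume(den, p))

  say("edge detection")
  edges <- detectEdges(den, gaussianSD = config$canny$sd,
                       weak = config$canny$weak, strong = config$canny$strong,
                       dilation = config$canny$dilation,
                       mode = config$canny$mode)

  say("myelin growing")
  V1 <- segmentMyelin(den, edges, maxSeedIntensity = config$bvg$myelinSeedMax,
                      deltaT = config$bvg$deltaT, seed = config$seed)

  say("seed extraction")
  B <- boundaryMask(edges, V1)
  seeds <- extractSeeds(B, vs)
  say("  %d seeds", nrow(seeds))

  say("serial volume growing")
  grown <- segmentVolume(den, B, seeds, deltaT = config$bvg$deltaT,
                         theta = config$bvg$theta, firstLabel = 2L)
  labels <- labelData(grown)
  labels[V1] <- 1L
  primary <- AxonSegmentation(labels, vs)
  ck("primary_labels.tif", function(p)
    writeLabels(primary, p, sub("\\.tif$", ".csv", p)))

  say("supervoxels + refinement")
  sv <- computeSupervoxels(den, compactness = config$slic$compactness,
                           step = config$slic$step)
  refined <- refineLabels(primary, sv, minLarge = config$refine$minLarge)
  ck("refined_labels.tif", function(p)
    writeLabels(refined, p, sub("\\.tif$", ".csv", p)))

  say("annotation")
  ann <- .annotateAll(den, refined, sv, config)
  seg <- ann$segmentation
  ck("annotated_labels.tif", function(p)
    writeLabels(seg, p, sub("\\.tif$", ".csv", p)))

  morph <- list()
  summaryDf <- NULL
  if (morphometry) {
    say("morphometry")
    tab <- segmentTable(seg)
    lab <- labelData(seg)
    myAx <- tab$id[tab$klass == "MYELINATED_AXON"]
    for (id in myAx) {
      mask <- lab == id
      mitos <- tab$id[tab$klass == "MITOCHONDRION" &
                      !is.na(tab$parent_axon_id) & tab$parent_axon_id == id]
      for (m in mitos) mask <- mask | lab == m
      mask <- fillHoles(mask)   # unlabelled shells around organelles
      res <- tryCatch({
        sk <- extractSkeleton(mask, vs, stepNm = config$skeleton$stepNm,
                              trimNm = config$skeleton$trimNm, axonId = id,
                              order = config$skeleton$order)
        axonMorphometry(mask, sk, vs,
                        lengthMinUm = config$morphometry$lengthMinUm,
                        every = config$morphometry$every)
      }, error = function(e) {
        say("  axon %d skipped: %s", id, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) morph[[as.character(id)]] <- res
    }
    if (length(morph)) {
      summaryDf <- do.call(rbind, lapply(morph, function(m)
        data.frame(axon = m$axonId, length_um = m$lengthUm,
                   included = m$included, t(m$medians))))
      rownames(summaryDf) <- NULL
      ck("morphometry_summary.csv", function(p)
        utils::write.csv(summaryDf, p, row.names = FALSE))
    }
  }

  volu <- tryCatch(volumetrics(seg), error = function(e) NULL)
  list(segmentation = seg, myelinMask = ann$myelin, morphometry = morph,
       summary = summaryDf, volumetrics = volu, supervoxels = NULL,
       config = config)
}

# annotation sub-pipeline: mitochondria by cavity closing on each large
# non-myelin segment, myelin redefinition, vacuole rule, axon
# classification, cell labelling of the unassigned leftovers
.annotateAll <- function(vol, refined, sv, config) {
  vs <- voxelSize(refined)
  labels <- labelData(refined)
  tab <- segmentTable(refined)
  an <- config$annotate

  myelinId <- 1L
  nextId <- max(c(tab$id, 1L)) + 1L
  mitoRows <- list()
  candidates <- tab$id[tab$id != myelinId &
                       tab$voxel_count > an$mitoMinParent]
  for (id in candidates) {
    mask <- labels == id
    mitos <- detectMitochondria(mask, sv, vs, closingRadius = an$closingNm,
                                minParent = an$mitoMinParent)
    for (m in mitos) {
      # claim only voxels not already owned by another refined segment
      m <- m[labels[m] %in% c(0L, myelinId)]
      if (length(m) == 0L) next
      labels[m] <- nextId
      mitoRows[[length(mitoRows) + 1L]] <-
        data.frame(id = nextId, klass = "MITOCHONDRION",
                   voxel_count = length(m), parent_axon_id = id,
                   review_flag = TRUE, stringsAsFactors = FALSE)
      nextId <- nextId + 1L
    }
  }

  MY <- labels == myelinId
  cells <- labelCells(labels == 0L, minSize = an$cellMin)
  nCells <- attr(cells, "n")
  cellRows <- list()
  if (nCells > 0L) {
    for (ci in seq_len(nCells)) {
      cid <- nextId
      labels[cells == ci] <- cid
      cellRows[[ci]] <- data.frame(id = cid, klass = "CELL",
                                   voxel_count = sum(cells == ci),
                                   parent_axon_id = NA_integer_,
                                   review_flag = FALSE,
                                   stringsAsFactors = FALSE)
      nextId <- nextId + 1L
    }
  }

  newTab <- tab
  newTab$klass[newTab$id == myelinId] <- "MYELIN"
  newTab$voxel_count <- tabulate(labels[labels > 0L],
                                 nbins = nextId - 1L)[newTab$id]
  newTab <- newTab[newTab$voxel_count > 0L, , drop = FALSE]
  extra <- c(mitoRows, cellRows)
  if (length(extra)) newTab <- rbind(newTab, do.call(rbind, extra))
  seg <- AxonSegmentation(labels, vs, newTab)

  seg <- classifyVacuoles(seg, vol, maxSize = an$vacuoleMax,
                          minMean = an$vacuoleMean)
  seg <- classifyAxons(seg, sv, MY, threshold = an$myelinFrac)

  # mitochondria parented by an unmyelinated axon keep the link; flag those
  # whose parent ended up neither axon class
  tab2 <- segmentTable(seg)
  axIds <- tab2$id[tab2$klass %in% c("MYELINATED_AXON", "UNMYELINATED_AXON")]
  bad <- tab2$klass == "MITOCHONDRION" & !(tab2$parent_axon_id %in% axIds)
  if (any(bad)) {
    tab2$review_flag[bad] <- TRUE
    tab2$parent_axon_id[bad] <- NA_integer_
    seg <- initialize(seg, segments = tab2)
  }
  list(segmentation = seg, myelin = MY)
}

#' Apply proof-reading overrides to flagged segments
#'
#' The automated mitochondria/axon-class calls carry review flags in place
#' of the interactive proof-reading step. Overrides are a data.frame (or CSV
#' path) with columns \code{id} and \code{accept}: a rejected mitochondrion
#' is returned to the myelin segment; a rejected myelinated-axon call flips
#' the class (and vice versa). Accepted rows just clear the flag.
#'
#' @param seg an annotated \linkS4class{AxonSegmentation}.
#' @param overrides data.frame or CSV path.
#' @return the updated segmentation.
#' @export
applyReview <- function(seg, overrides) {
  if (is.character(overrides))
    overrides <- utils::read.csv(overrides, stringsAsFactors = FALSE)
  tab <- segmentTable(seg)
  labels <- labelData(seg)
  myelinId <- tab$id[tab$klass == "MYELIN"][1L]
  for (r in seq_len(nrow(overrides))) {
    id <- overrides$id[r]
    i <- match(id, tab$id)
    if (is.na(i)) next
    if (isTRUE(as.logical(overrides$accept[r]))) {
      tab$review_flag[i] <- FALSE
      next
    }
    if (tab$klass[i] == "MITOCHONDRION" && !is.na(myelinId)) {
      labels[labels == id] <- myelinId
      tab$voxel_count[tab$id == myelinId] <-
        tab$voxel_count[tab$id == myelinId] + tab$voxel_count[i]
      tab <- tab[-i, , drop = FALSE]
    } else if (tab$klass[i] == "MYELINATED_AXON") {
      tab$klass[i] <- "UNMYELINATED_AXON"; tab$review_flag[i] <- FALSE
    } else if (tab$klass[i] == "UNMYELINATED_AXON") {
      tab$klass[i] <- "MYELINATED_AXON"; tab$review_flag[i] <- FALSE
    }
  }
  AxonSegmentation(labels, voxelSize(seg), tab)
}
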