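#' Nucleus segmentation for the reference cell backend
#'
#' Segments nuclei on the hematoxylin density channel: the channel is
#' Gaussian-smoothed, thresholded at a fixed density (0.35 OD, well above the
#' background of both stained and unstained tissue), hole-filled, and split
#' into instances by watershed on the distance map. Instances below a minimum
#' area are discarded.
#'
#' @param px 800 x 800 x 3 tile pixel array.
#' @param minArea minimum instance area in pixels.
#' @return A list with `masks` (list of pixel-index vectors) and the stain
#'   channel matrices `hema`, `dab`.
#' @export
segmentNuclei <- function(px, minArea = 15L) {
  ch <- stainChannels(px)
  sm <- EBImage::gblur(ch$hema, sigma = 1)
  bin <- sm > 0.35
  if (!any(bin)) {
    return(list(masks = list(), hema = ch$hema, dab = ch$dab))
  }
  bin <- EBImage::fillHull(bin)
  seg <- EBImage::watershed(EBImage::distmap(bin), tolerance = 1, ext = 1)
  seg <- as.matrix(seg)
  ids <- seq_len(max(seg))
  areas <- tabulate(seg[seg > 0L], nbins = max(seg))
  keep <- ids[areas >= minArea]
  masks <- lapply(keep, function(id) which(seg == id))
  list(masks = masks, hema = ch$hema, dab = ch$dab)
}

# Per-instance features: size, shape and stain statistics.
instanceFeatures <- function(masks, hema, dab) {
  ts <- tileSize()
  out <- matrix(NA_real_, length(masks), 5,
                dimnames = list(NULL, c("logArea", "ecc", "meanH",
                                        "dabNuc", "dabRing")))
  nucAll <- matrix(FALSE, ts, ts)
  for (m in masks) nucAll[m] <- TRUE
  for (k in seq_along(masks)) {
    m <- masks[[k]]
    ys <- (m - 1L) %% ts
    xs <- (m - 1L) %/% ts
    cv <- stats::cov(cbind(xs, ys))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 1e-6)
    x0 <- max(min(xs) - 5L, 0L); x1 <- min(max(xs) + 5L, ts - 1L)
    y0 <- max(min(ys) - 5L, 0L); y1 <- min(max(ys) + 5L, ts - 1L)
    box <- as.vector(outer((y0:y1) + 1L, (x0:x1) * ts, "+"))
    ring <- box[!nucAll[box]]
    out[k, ] <- c(
      logArea = log(length(m)),
      ecc = sqrt(1 - ev[2] / ev[1]),
      meanH = mean(hema[m]),
      dabNuc = mean(dab[m]),
      dabRing = if (length(ring)) mean(dab[ring]) else 0
    )
  }
  out
}

#' Oracle cell model
#'
#' A [CellModel-class] that emits the planted ground truth of synthetic
#' slides as detections (confidence 1). Used to exercise the scoring and
#' statistics stages independently of detector quality.
#'
#' @param truths named list of [GroundTruth-class] objects, keyed by slide id.
#' @return A `CellModel` with backend `"oracle"`.
#' @export
oracleCellModel <- function(truths) {
  stopifnot(length(names(truths)) == length(truths))
  new("CellModel", backend = "oracle", fit = list(truths = truths),
      seed = NA_integer_)
}

#' Train the reference cell detector / classifier
#'
#' Fits the reference backend: nuclei are segmented with [segmentNuclei()],
#' segmented instances are matched to the annotated cells (IoU at least
#' `iouThreshold`), and two linear discriminants are fitted on the matched
#' instances: tumor vs non-tumor on size/shape/hematoxylin features, and
#' PTEN-positive vs negative on nuclear and perinuclear DAB density.
#'
#' @param tiles list of [Tile-class] training tiles.
#' @param annotations list of cell tables (one per tile; see [cellTable()]).
#' @param iouThreshold IoU used to transfer annotation labels to segmented
#'   instances.
#' @param seed integer, recorded on the model.
#' @return A fitted [CellModel-class] with backend `"segmentation"`.
#' @export
trainCellModel <- function(tiles, annotations, iouThreshold = 0.5, seed = 1L) {
  stopifnot(length(tiles) == length(annotations))
  allCls <- unlist(lapply(annotations, function(a) a$class))
  if (length(allCls) == 0L) stop("no cell annotations supplied")
  missing <- setdiff(ptenClasses(), allCls)
  if (length(missing)) {
    stop("training annotations must contain every class; missing: ",
         paste(missing, collapse = ", "))
  }
  withSeed(seed, {
    feats <- NULL; labs <- character()
    for (k in seq_along(tiles)) {
      seg <- segmentNuclei(tilePixels(tiles[[k]]))
      if (length(seg$masks) == 0L) next
      ann <- annotations[[k]]
      hit <- matchDetections(seg$masks, rep(1, length(seg$masks)),
                             as.list(ann$mask), iouThreshold)
      ok <- !is.na(hit)
      if (!any(ok)) next
      f <- instanceFeatures(seg$masks[ok], seg$hema, seg$dab)
      feats <- rbind(feats, f)
      labs <- c(labs, ann$class[hit[ok]])
    }
    tumGrp <- factor(ifelse(startsWith(labs, "tumor"), "tumor", "nontumor"),
                     levels = c("nontumor", "tumor"))
    posGrp <- factor(ifelse(endsWith(labs, "_pos"), "pos", "neg"),
                     levels = c("neg", "pos"))
    if (nlevels(droplevels(tumGrp)) < 2L || nlevels(droplevels(posGrp)) < 2L) {
      stop("segmentation recovered annotated cells from fewer than two ",
           "classes; cannot fit the classifiers")
    }
    tumorLda <- suppressWarnings(
      MASS::lda(x = feats[, c("logArea", "ecc", "meanH"), drop = FALSE],
                grouping = tumGrp))
    posLda <- suppressWarnings(
      MASS::lda(x = feats[, c("dabNuc", "dabRing"), drop = FALSE],
                grouping = posGrp))
    new("CellModel", backend = "segmentation",
        fit = list(tumorLda = tumorLda, posLda = posLda,
                   iouThreshold = iouThreshold),
        seed = as.integer(seed))
  })
}

#' Detect and classify cells in a tile
#'
#' Runs the model backend on one tile and returns a cell table of detections
#' (four-class labels with confidences). Overlapping proposals are resolved
#' by confidence-ranked non-maximum suppression at IoU 0.5. Deterministic for
#' a fixed model. Passing a non-tumor tile is allowed (the pipeline filters
#' upstream); the result is then flagged in its metadata.
#'
#' @param model a fitted [CellModel-class].
#' @param tile a [Tile-class].
#' @return A cell table (see [cellTable()]); empty for a blank tile.
#' @export
detectCells <- function(model, tile) {
  stopifnot(is(model, "CellModel"), is(tile, "Tile"))
  out <- switch(model@backend,
    oracle = {
      truth <- model@fit$truths[[tile@slideId]]
      if (is.null(truth)) stop("oracle model has no truth for slide ",
                               tile@slideId)
      tileCellTable(truth, tile)
    },
    segmentation = {
      seg <- segmentNuclei(tilePixels(tile))
      if (length(seg$masks) == 0L) {
        cellTable()
      } else {
        f <- instanceFeatures(seg$masks, seg$hema, seg$dab)
        pt <- stats::predict(model@fit$tumorLda,
                             newdata = f[, c("logArea", "ecc", "meanH"),
                                         drop = FALSE])$posterior[, "tumor"]
        pp <- stats::predict(model@fit$posLda,
                             newdata = f[, c("dabNuc", "dabRing"),
                                         drop = FALSE])$posterior[, "pos"]
        cls <- paste0(ifelse(pt >= 0.5, "tumor", "nontumor"),
                      ifelse(pp >= 0.5, "_pos", "_neg"))
        conf <- pmax(pt, 1 - pt) * pmax(pp, 1 - pp)
        suppressDetections(
          cellTable(class = cls, confidence = conf, mask = seg$masks))
      }
    },
    stop("unknown cell-model backend: ", model@backend)
  )
  if (tileLabel(tile) == "non-tumor") {
    S4Vectors::metadata(out)$nonTumorTile <- TRUE
  }
  out
}

#' Non-maximum suppression on a cell table
#'
#' Greedy suppression: detections are visited in decreasing confidence order
#' (stable on ties) and a detection is dropped when its mask IoU with an
#' already kept detection is at least `iouThreshold`.
#'
#' @param det a cell table of detections.
#' @param iouThreshold suppression threshold.
#' @return The surviving subset, in original row order.
#' @export
suppressDetections <- function(det, iouThreshold = 0.5) {
  n <- nrow(det)
  if (n <= 1L) return(det)
  masks <- scopedMasks(det)
  ord <- order(-det$confidence, seq_len(n))
  keep <- logical(n)
  for (d in ord) {
    clash <- FALSE
    for (k in which(keep)) {
      if (maskIoU(masks[[d]], masks[[k]]) >= iouThreshold) {
        clash <- TRUE
        break
      }
    }
    if (!clash) keep[d] <- TRUE
  }
  det[keep, , drop = FALSE]
}

#' One round of annotation refinement
#'
#' Applies a trained model to annotated tiles; detections whose IoU with
#' every original annotation in their tile is below `iouThreshold` are
#' "unmatched" (an overlap exactly at the threshold counts as matched). Each
#' unmatched detection must receive a reviewer-assigned four-class label; the
#' labeled unmatched detections are merged with the original annotations for
#' a second training round, so the merged set never shrinks.
#'
#' @param model a fitted [CellModel-class].
#' @param tiles list of [Tile-class] objects.
#' @param annotations list of cell tables, one per tile.
#' @param reviewer function(tileIndex, mask) returning a class from
#'   [ptenClasses()] for an unmatched detection (in tests, a ground-truth
#'   lookup); an `NA` return is rejected.
#' @param iouThreshold matching threshold.
#' @return An [AnnotationRevision-class].
#' @export
refineAnnotations <- function(model, tiles, annotations, reviewer,
                              iouThreshold = 0.5) {
  stopifnot(length(tiles) == length(annotations), is.function(reviewer))
  origs <- vector("list", length(tiles))
  unms <- list()
  for (k in seq_along(tiles)) {
    ann <- annotations[[k]]
    ann$tile <- rep(k, nrow(ann))
    origs[[k]] <- ann
    det <- detectCells(model, tiles[[k]])
    if (nrow(det) == 0L) next
    annMasks <- as.list(annotations[[k]]$mask)
    for (d in seq_len(nrow(det))) {
      dm <- det$mask[[d]]
      best <- if (length(annMasks)) {
        max(vapply(annMasks, maskIoU, numeric(1), b = dm))
      } else {
        0
      }
      if (best < iouThreshold) {
        lab <- reviewer(k, dm)
        if (is.na(lab) || !lab %in% ptenClasses()) {
          stop("unmatched detection in tile ", k,
               " lacks a valid reviewer label")
        }
        unms[[length(unms) + 1L]] <- cellTable(
          class = lab, confidence = det$confidence[d],
          mask = list(dm), tile = k)
      }
    }
  }
  empty <- cellTable(tile = integer())
  origPool <- if (length(origs)) do.call(rbind, origs) else empty
  unmPool <- if (length(unms)) do.call(rbind, unms) else empty
  merged <- rbind(origPool, unmPool)
  new("AnnotationRevision", original = origPool, unmatched = unmPool,
      merged = merged, iouThreshold = iouThreshold)
}

#' Ground-truth reviewer for refinement tests
#'
#' Builds a reviewer function from a slide's ground truth: an unmatched
#' detection is labeled with the class of the planted cell its mask overlaps
#' most, falling back to a non-tumor label for detections on background.
#'
#' @param truth a [GroundTruth-class].
#' @param tiles the tile list the reviewer will be called with.
#' @return A function(tileIndex, mask) -> class label.
#' @export
groundTruthReviewer <- function(truth, tiles) {
  function(tileIdx, mask) {
    tile <- tiles[[tileIdx]]
    ts <- tileSize()
    sub <- instanceMask(truth)[(tile@y + 1L):(tile@y + ts),
                               (tile@x + 1L):(tile@x + ts), drop = FALSE]
    ids <- sub[mask]
    ids <- ids[ids > 0L]
    if (length(ids)) {
      id <- as.integer(names(which.max(table(ids))))
      cells(truth)$class[match(id, cells(truth)$cell)]
    } else {
      "nontumor_neg"
    }
  }
}
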