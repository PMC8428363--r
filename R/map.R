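#' Mean average precision of cell detections
#'
#' Instance-segmentation evaluation: for each of the four cell classes,
#' detections are ranked by decreasing confidence and matched greedily to
#' ground-truth instances of the same class (a detection matches the free
#' truth instance of highest IoU, provided IoU is at least `iouThreshold`;
#' each truth instance is consumed at most once). Average precision is
#' computed from the resulting precision-recall curve with all-point
#' interpolation (the precision envelope), and mAP is the unweighted mean of
#' the per-class APs over the classes present in the truth. Masks carry an
#' optional `tile` column so multi-tile sets are matched within tiles only.
#'
#' @param detections cell table of detections (class, confidence, mask, and
#'   optionally tile).
#' @param truth cell table of ground-truth instances (same mask space).
#' @param iouThreshold IoU matching threshold (boundary-inclusive),
#'   default 0.5.
#' @return A list: `mAP`, and `perClass` (named numeric vector of APs).
#' @export
#' @examples
#' tr <- cellTable(class = "tumor_pos", confidence = 1, mask = list(1:20))
#' meanAveragePrecision(tr, tr)$mAP
meanAveragePrecision <- function(detections, truth, iouThreshold = 0.5) {
  if (nrow(truth) == 0L) stop("ground truth must be non-empty")
  classes <- intersect(ptenClasses(), unique(truth$class))
  detMasks <- scopedMasks(detections)
  truMasks <- scopedMasks(truth)
  ap <- vapply(classes, function(cl) {
    tIdx <- which(truth$class == cl)
    dIdx <- which(detections$class == cl)
    averagePrecision(detMasks[dIdx], detections$confidence[dIdx],
                     truMasks[tIdx], iouThreshold)
  }, numeric(1))
  names(ap) <- classes
  list(mAP = mean(ap), perClass = ap)
}

# AP for one class from ranked detections (all-point interpolation).
averagePrecision <- function(detMasks, detConf, truthMasks, iouThreshold) {
  nt <- length(truthMasks)
  if (nt == 0L) return(NA_real_)
  nd <- length(detMasks)
  if (nd == 0L) return(0)
  matched <- matchDetections(detMasks, detConf, truthMasks, iouThreshold)
  ord <- order(-detConf, seq_len(nd))
  tp <- !is.na(matched[ord])
  cumTp <- cumsum(tp)
  prec <- cumTp / seq_len(nd)
  rec <- cumTp / nt
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}
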