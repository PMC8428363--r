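# Instance-mask helpers.
#
# A mask is a set of 1-based linear pixel indices into an 800 x 800 tile
# matrix (column-major, rows = y): index = 800 * x + y + 1 for 0-based tile
# coordinates (x, y). Masks from different tiles are never compared directly;
# the optional `tile` column of a cell table scopes them.

#' Intersection-over-union of two pixel-index masks
#'
#' @param a,b integer vectors of pixel indices (duplicates ignored).
#' @return IoU in `[0, 1]`; 0 when both masks are empty.
#' @export
#' @examples
#' maskIoU(1:10, 6:15)
maskIoU <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(0)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

# tile-scoped ids so masks in different tiles never collide
scopedMasks <- function(tbl) {
  masks <- as.list(tbl$mask)
  if (!is.null(tbl$tile)) {
    tilespan <- tileSize()^2
    masks <- mapply(function(m, t) as.numeric(m) + as.numeric(t) * tilespan,
                    masks, tbl$tile, SIMPLIFY = FALSE)
  }
  masks
}

#' Run-length encode a mask
#'
#' Encodes a pixel-index mask as alternating (start, length) pairs over the
#' sorted indices, the plain-text interchange format used by the cell-table
#' readers and writers.
#'
#' @param idx integer vector of pixel indices.
#' @return Integer vector `c(start1, len1, start2, len2, ...)`.
#' @export
#' @examples
#' maskToRle(c(1:3, 10:12))
maskToRle <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  if (length(idx) == 0L) return(integer())
  breaks <- c(TRUE, diff(idx) != 1L)
  starts <- idx[breaks]
  lens <- diff(c(which(breaks), length(idx) + 1L))
  as.integer(rbind(starts, lens))
}

#' @rdname maskToRle
#' @param rle integer vector of (start, length) pairs.
#' @export
rleToMask <- function(rle) {
  if (length(rle) == 0L) return(integer())
  stopifnot(length(rle) %% 2L == 0L)
  starts <- rle[seq(1L, length(rle), by = 2L)]
  lens <- rle[seq(2L, length(rle), by = 2L)]
  as.integer(unlist(mapply(function(s, l) seq.int(s, length.out = l),
                           starts, lens, SIMPLIFY = FALSE)))
}

# Greedy confidence-ranked matching of detections to truth instances.
# Returns, for detections sorted by decreasing confidence, the index of the
# matched truth instance (NA when unmatched). A truth instance is consumed by
# at most one detection; a detection matches the highest-IoU free truth with
# IoU >= threshold (boundary-inclusive). `order` breaks confidence ties by
# original position (stable).
matchDetections <- function(detMasks, detConf, truthMasks, iouThreshold = 0.5) {
  nd <- length(detMasks); nt <- length(truthMasks)
  ord <- order(-detConf, seq_len(nd))
  matched <- rep(NA_integer_, nd)
  free <- rep(TRUE, nt)
  for (d in ord) {
    if (!any(free)) break
    best <- NA_integer_; bestIoU <- -1
    for (t in which(free)) {
      iou <- maskIoU(detMasks[[d]], truthMasks[[t]])
      if (iou > bestIoU) {
        bestIoU <- iou
        best <- t
      }
    }
    if (!is.na(best) && bestIoU >= iouThreshold) {
      matched[d] <- best
      free[best] <- FALSE
    }
  }
  matched
}
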