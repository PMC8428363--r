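#' Specify a synthetic IHC slide
#'
#' Parameters for the synthetic-slide generator. The rendered slides emulate
#' PTEN immunohistochemistry of prostate tissue: hematoxylin-blue nuclei for
#' every cell, with DAB-brown cytoplasmic and nuclear signal added to
#' PTEN-positive cells; tumor nuclei are larger than non-tumor nuclei.
#' Technical-failure slides reproduce reduced (`low_antibody`) or absent
#' (`no_antibody`) DAB staining.
#'
#' @param widthPx,heightPx slide dimensions in pixels; must be at least 800
#'   when any tumor region is requested.
#' @param mpp microns per pixel; the default 0.227 corresponds to a 40x scan.
#' @param nTumorRegions number of tumor regions (jittered-rectangle polygons).
#' @param positiveFraction probability that a tumor cell is PTEN-positive,
#'   in `[0, 1]`.
#' @param tumorCellDensity expected tumor cells per 800 x 800 tile of tumor
#'   region.
#' @param nontumorCellDensity expected non-tumor cells per tile outside tumor
#'   regions.
#' @param nontumorPositiveFraction probability that a non-tumor cell is
#'   PTEN-positive; defaults high because PTEN is retained in benign tissue.
#' @param tumorRegionCover `"random"` places jittered-rectangle regions of
#'   35-60% of the slide's short side; `"full"` makes a single region
#'   covering the whole slide (convenient for building pure tumor tiles).
#' @param failureMode `"none"`, `"low_antibody"` (DAB attenuated) or
#'   `"no_antibody"` (no DAB signal).
#' @param seed integer seed; identical specs give bit-identical slides.
#' @return A validated list of class `"SlideSpec"`.
#' @export
#' @examples
#' slideSpec(widthPx = 800, heightPx = 800, positiveFraction = 0.8, seed = 1)
slideSpec <- function(widthPx = 1600L, heightPx = 1600L, mpp = 0.227,
                      nTumorRegions = 1L, positiveFraction = 0.8,
                      tumorCellDensity = 60, nontumorCellDensity = 40,
                      nontumorPositiveFraction = 0.9,
                      tumorRegionCover = c("random", "full"),
                      failureMode = c("none", "low_antibody", "no_antibody"),
                      seed = 1L) {
  failureMode <- match.arg(failureMode)
  tumorRegionCover <- match.arg(tumorRegionCover)
  widthPx <- as.integer(widthPx); heightPx <- as.integer(heightPx)
  if (widthPx < 1L || heightPx < 1L) stop("slide dimensions must be positive")
  if (positiveFraction < 0 || positiveFraction > 1) {
    stop("positiveFraction must lie in [0, 1]")
  }
  if (nontumorPositiveFraction < 0 || nontumorPositiveFraction > 1) {
    stop("nontumorPositiveFraction must lie in [0, 1]")
  }
  if (nTumorRegions < 0L) stop("nTumorRegions must be >= 0")
  if (nTumorRegions > 0L && (widthPx < tileSize() || heightPx < tileSize())) {
    stop("tumor region larger than image: slide must be at least 800 x 800 ",
         "pixels when a tumor region is requested")
  }
  structure(list(
    widthPx = widthPx, heightPx = heightPx, mpp = mpp,
    nTumorRegions = as.integer(nTumorRegions),
    positiveFraction = positiveFraction,
    tumorCellDensity = tumorCellDensity,
    nontumorCellDensity = nontumorCellDensity,
    nontumorPositiveFraction = nontumorPositiveFraction,
    tumorRegionCover = tumorRegionCover,
    failureMode = failureMode, seed = as.integer(seed)
  ), class = "SlideSpec")
}

# Jittered-rectangle tumor polygons that fit inside the image.
sampleTumorPolygons <- function(n, w, h) {
  polys <- vector("list", n)
  for (k in seq_len(n)) {
    rw <- stats::runif(1, 0.35, 0.6) * min(w, h)
    rh <- stats::runif(1, 0.35, 0.6) * min(w, h)
    x0 <- stats::runif(1, 0, w - 1 - rw)
    y0 <- stats::runif(1, 0, h - 1 - rh)
    jit <- function() stats::runif(1, -0.05, 0.05) * min(rw, rh)
    poly <- rbind(
      c(x0 + jit(), y0 + jit()),
      c(x0 + rw + jit(), y0 + jit()),
      c(x0 + rw + jit(), y0 + rh + jit()),
      c(x0 + jit(), y0 + rh + jit())
    )
    poly[, 1] <- pmin(pmax(poly[, 1], 0), w - 1)
    poly[, 2] <- pmin(pmax(poly[, 2], 0), h - 1)
    colnames(poly) <- c("x", "y")
    polys[[k]] <- poly
  }
  polys
}

# Candidate cell centers: jittered grid with guaranteed separation, kept away
# from image borders and tile-grid lines so each nucleus lies in one tile.
sampleCellCenters <- function(w, h, spacing = 26, jitter = 2, margin = 12) {
  gx <- seq(spacing / 2, w - 1 - spacing / 2, by = spacing)
  gy <- seq(spacing / 2, h - 1 - spacing / 2, by = spacing)
  if (length(gx) == 0L || length(gy) == 0L) {
    return(cbind(x = numeric(), y = numeric()))
  }
  grid <- expand.grid(x = gx, y = gy)
  cx <- grid$x + stats::runif(nrow(grid), -jitter, jitter)
  cy <- grid$y + stats::runif(nrow(grid), -jitter, jitter)
  ok <- cx >= margin & cx <= w - 1 - margin &
    cy >= margin & cy <= h - 1 - margin &
    (cx %% tileSize()) >= margin & (cx %% tileSize()) <= tileSize() - margin &
    (cy %% tileSize()) >= margin & (cy %% tileSize()) <= tileSize() - margin
  cbind(x = cx[ok], y = cy[ok])
}

#' Generate a synthetic IHC slide with per-cell ground truth
#'
#' Renders an RGB slide by Beer-Lambert composition of hematoxylin and DAB
#' optical densities and returns it together with the full ground truth:
#' tumor polygons, the per-cell class table (the four PTEN classes), and a
#' pixel-level instance mask. Tumor-class cells are placed only inside tumor
#' polygons, non-tumor cells only outside. Identical specs (including seed)
#' produce bit-identical output.
#'
#' @param spec a [slideSpec()].
#' @param slideId identifier stored on the returned objects.
#' @return A list with elements `slide` ([SlideImage-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
#' @examples
#' s <- generateSlide(slideSpec(widthPx = 800, heightPx = 800, seed = 3))
#' s$slide
#' table(cells(s$truth)$class)
generateSlide <- function(spec, slideId = "synthetic") {
  stopifnot(inherits(spec, "SlideSpec"))
  withSeed(spec$seed, {
    w <- spec$widthPx; h <- spec$heightPx
    polys <- if (spec$nTumorRegions > 0L &&
                 identical(spec$tumorRegionCover, "full")) {
      full <- cbind(x = c(0, w - 1, w - 1, 0), y = c(0, 0, h - 1, h - 1))
      list(full)
    } else {
      sampleTumorPolygons(spec$nTumorRegions, w, h)
    }

    centers <- sampleCellCenters(w, h)
    inTumor <- if (length(polys)) {
      pointInAnyPolygon(centers[, 1], centers[, 2], polys)
    } else {
      rep(FALSE, nrow(centers))
    }
    slotsPerTile <- (tileSize() / 26)^2
    keepT <- inTumor &
      stats::runif(nrow(centers)) < min(1, spec$tumorCellDensity / slotsPerTile)
    keepN <- !inTumor &
      stats::runif(nrow(centers)) < min(1, spec$nontumorCellDensity / slotsPerTile)

    nT <- sum(keepT); nN <- sum(keepN)
    cls <- character(nT + nN)
    cx <- c(centers[keepT, 1], centers[keepN, 1])
    cy <- c(centers[keepT, 2], centers[keepN, 2])
    if (nT > 0) {
      pos <- stats::runif(nT) < spec$positiveFraction
      cls[seq_len(nT)] <- ifelse(pos, "tumor_pos", "tumor_neg")
    }
    if (nN > 0) {
      pos <- stats::runif(nN) < spec$nontumorPositiveFraction
      cls[nT + seq_len(nN)] <- ifelse(pos, "nontumor_pos", "nontumor_neg")
    }
    isTum <- seq_along(cls) <= nT
    a <- ifelse(isTum, stats::runif(length(cls), 6.5, 9.5),
                stats::runif(length(cls), 4.0, 5.8))
    b <- a * stats::runif(length(cls), 0.70, 0.95)
    theta <- stats::runif(length(cls), 0, pi)
    ph1 <- stats::runif(length(cls), 0, 2 * pi)
    ph2 <- stats::runif(length(cls), 0, 2 * pi)

    # accumulate stain densities
    hema <- matrix(pmax(stats::rnorm(h * w, 0.05, 0.008), 0), h, w)
    dab <- matrix(0, h, w)
    imask <- matrix(0L, h, w)
    tau <- switch(spec$failureMode, none = 1, low_antibody = 0.25, no_antibody = 0)

    for (k in seq_along(cls)) {
      r <- ceiling(a[k] * 1.5) + 2
      xs <- max(0, floor(cx[k] - r)):min(w - 1, ceiling(cx[k] + r))
      ys <- max(0, floor(cy[k] - r)):min(h - 1, ceiling(cy[k] + r))
      px <- rep(xs, each = length(ys))
      py <- rep(ys, times = length(xs))
      dx <- px - cx[k]; dy <- py - cy[k]
      u <- dx * cos(theta[k]) + dy * sin(theta[k])
      v <- -dx * sin(theta[k]) + dy * cos(theta[k])
      rr <- sqrt((u / a[k])^2 + (v / b[k])^2)
      phi <- atan2(v, u)
      f <- 1 + 0.07 * sin(3 * phi + ph1[k]) + 0.05 * sin(2 * phi + ph2[k])
      nuc <- rr <= f
      ring <- rr > f & rr <= 1.45 * f
      lin <- py + 1L + h * px # column-major index into h x w matrices
      nl <- lin[nuc]
      hema[nl] <- stats::runif(length(nl), 0.85, 1.15) * 0.8
      if (cls[k] %in% c("tumor_pos", "nontumor_pos") && tau > 0) {
        dab[nl] <- dab[nl] + 0.35 * tau
        rl <- lin[ring]
        dab[rl] <- dab[rl] + stats::runif(length(rl), 0.85, 1.15) * 0.45 * tau
      }
      imask[nl] <- k
    }

    img <- composeStains(hema, dab)
    slide <- new("SlideImage", image = img, mpp = spec$mpp,
                 slideId = slideId, failureMode = spec$failureMode)
    cellsDf <- data.frame(
      cell = seq_along(cls), class = cls, x = cx, y = cy,
      a = a, b = b, theta = theta, stringsAsFactors = FALSE
    )
    truth <- new("GroundTruth", polygons = polys, cells = cellsDf,
                 instanceMask = imask, failure = spec$failureMode != "none")
    list(slide = slide, truth = truth)
  })
}

#' Planted PTEN score of a synthetic slide
#'
#' The fraction of tumor-class cells that are PTEN-positive in the ground
#' truth; `NA` when the slide carries no tumor cells.
#'
#' @param truth a [GroundTruth-class].
#' @return A number in `[0, 1]`, or `NA`.
#' @export
plantedScore <- function(truth) {
  cl <- cells(truth)$class
  npos <- sum(cl == "tumor_pos"); nneg <- sum(cl == "tumor_neg")
  if (npos + nneg == 0L) return(NA_real_)
  npos / (npos + nneg)
}
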