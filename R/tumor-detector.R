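#' Tile feature extraction for the reference tumor detector
#'
#' Summarizes a tile by stain-channel statistics and nuclear-blob texture:
#' moments and coverage of the hematoxylin and DAB density channels, and the
#' count and mean area of connected nuclear blobs. Tumor tiles carry larger,
#' denser nuclei than benign tissue, which these summaries separate.
#'
#' @param tile a [Tile-class] (or an 800 x 800 x 3 array).
#' @return Named numeric vector of features.
#' @export
tileFeatures <- function(tile) {
  px <- if (is(tile, "Tile")) tilePixels(tile) else tile
  if (length(dim(px)) != 3L || dim(px)[1] != tileSize() ||
      dim(px)[2] != tileSize() || dim(px)[3] != 3L) {
    stop("tile payload must be an 800 x 800 x 3 array")
  }
  ch <- stainChannels(px)
  nucBin <- ch$hema > 0.35
  lab <- EBImage::bwlabel(nucBin)
  nBlob <- max(lab)
  areas <- if (nBlob > 0) tabulate(lab[lab > 0L]) else numeric()
  c(
    meanH = mean(ch$hema), sdH = stats::sd(ch$hema),
    covH = mean(nucBin), q90H = unname(stats::quantile(ch$hema, 0.9)),
    meanD = mean(ch$dab), sdD = stats::sd(ch$dab),
    covD = mean(ch$dab > 0.15),
    nBlob = nBlob,
    meanBlobArea = if (nBlob > 0) mean(areas) else 0,
    q90BlobArea = if (nBlob > 0) unname(stats::quantile(areas, 0.9)) else 0
  )
}

#' Train the tumor-tile detector
#'
#' Fits the reference backend: linear discriminant analysis on
#' [tileFeatures()]. Unlabeled tiles are excluded from fitting; at least two
#' classes must remain. Training is deterministic for a fixed seed and
#' feature set.
#'
#' @param tiles list of [Tile-class] objects.
#' @param labels optional character vector of labels (`"tumor"` /
#'   `"non-tumor"`); defaults to the tiles' own labels.
#' @param threshold decision threshold on the tumor probability.
#' @param seed integer, recorded on the model.
#' @return A fitted [TileClassifier-class].
#' @export
trainTileClassifier <- function(tiles, labels = NULL, threshold = 0.5,
                                seed = 1L) {
  if (is.null(labels)) labels <- vapply(tiles, tileLabel, character(1))
  stopifnot(length(labels) == length(tiles))
  keep <- labels %in% c("tumor", "non-tumor")
  if (length(unique(labels[keep])) < 2L) {
    stop("training requires both tumor and non-tumor tiles")
  }
  withSeed(seed, {
    feats <- t(vapply(tiles[keep], tileFeatures, tileFeatures(tiles[[1]])))
    y <- factor(labels[keep], levels = c("non-tumor", "tumor"))
    ctr <- colMeans(feats)
    scl <- apply(feats, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    z <- scale(feats, center = ctr, scale = scl)
    # keep features with genuine spread within each class, mirroring the
    # constant-within-group guard of the discriminant fit
    usable <- apply(z, 2, function(v) {
      s <- tapply(v, y, stats::sd)
      isTRUE(stats::sd(v) > 1e-8) && isTRUE(all(!is.na(s) & s > 1e-3))
    })
    if (!any(usable)) stop("no informative tile features")
    # prune near-collinear features greedily: with few training tiles the
    # pooled covariance is otherwise near-singular and the discriminant
    # weights explode, extrapolating wildly outside the training range
    kept <- integer()
    for (j in which(usable)) {
      if (!length(kept) ||
          all(abs(stats::cor(z[, j], z[, kept, drop = FALSE])) < 0.95)) {
        kept <- c(kept, j)
      }
    }
    usable <- seq_len(ncol(z)) %in% kept
    fit <- suppressWarnings(
      MASS::lda(x = z[, usable, drop = FALSE], grouping = y)
    )
    new("TileClassifier", backend = "lda", threshold = threshold,
        fit = list(lda = fit, features = colnames(feats)[usable],
                   center = ctr, scale = scl),
        seed = as.integer(seed))
  })
}

#' Predict the tumor probability of a tile
#'
#' @param model a fitted [TileClassifier-class].
#' @param tile a [Tile-class] (or 800 x 800 x 3 array).
#' @return Probability in `[0, 1]` that the tile is a tumor tile;
#'   deterministic for a fixed model.
#' @export
predictTile <- function(model, tile) {
  stopifnot(is(model, "TileClassifier"))
  if (length(model@fit) == 0L) stop("model is not fitted")
  f <- tileFeatures(tile)
  z <- (f - model@fit$center) / model@fit$scale
  z <- z[model@fit$features, drop = FALSE]
  p <- stats::predict(model@fit$lda, newdata = rbind(z))$posterior[, "tumor"]
  unname(pmin(pmax(p, 0), 1))
}

#' @rdname predictTile
#' @return `classifyTile`: `"tumor"` when the probability is at least the
#'   model threshold, `"non-tumor"` otherwise.
#' @export
classifyTile <- function(model, tile) {
  if (predictTile(model, tile) >= model@threshold) "tumor" else "non-tumor"
}

#' Proportion of tiles correctly classified
#'
#' @param model a fitted [TileClassifier-class].
#' @param tiles list of tiles with reference labels.
#' @param labels optional labels overriding the tiles' own.
#' @return Proportion correct among labeled tiles, in `[0, 1]`.
#' @export
tileAccuracy <- function(model, tiles, labels = NULL) {
  if (is.null(labels)) labels <- vapply(tiles, tileLabel, character(1))
  keep <- labels %in% c("tumor", "non-tumor")
  if (!any(keep)) stop("no labeled tiles to evaluate")
  pred <- vapply(tiles[keep], function(t) classifyTile(model, t), character(1))
  mean(pred == labels[keep])
}
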