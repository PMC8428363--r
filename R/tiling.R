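#' Partition a slide into non-overlapping 800 x 800 tiles
#'
#' The tile grid is anchored at the slide origin; right and bottom remainder
#' pixels that do not fill a whole tile are dropped, so a `W x H` slide yields
#' `floor(W/800) * floor(H/800)` tiles and every returned pixel belongs to
#' exactly one tile.
#'
#' @param slide a [SlideImage-class].
#' @return A list of [Tile-class] objects, row-major (j, then i).
#' @export
#' @examples
#' s <- generateSlide(slideSpec(widthPx = 800, heightPx = 800, seed = 1))
#' length(partitionTiles(s$slide))
partitionTiles <- function(slide) {
  stopifnot(is(slide, "SlideImage"))
  img <- slidePixels(slide)
  h <- dim(img)[1]; w <- dim(img)[2]
  ts <- tileSize()
  ni <- w %/% ts; nj <- h %/% ts
  tiles <- vector("list", ni * nj)
  k <- 0L
  for (j in seq_len(nj) - 1L) {
    for (i in seq_len(ni) - 1L) {
      k <- k + 1L
      x0 <- i * ts; y0 <- j * ts
      tiles[[k]] <- new("Tile",
        slideId = slideId(slide), i = i, j = j,
        x = x0, y = y0,
        pixels = img[(y0 + 1L):(y0 + ts), (x0 + 1L):(x0 + ts), , drop = FALSE],
        label = "unlabeled"
      )
    }
  }
  tiles
}

#' Label a tile as tumor or non-tumor from polygon annotations
#'
#' A tile is a tumor tile if and only if its center point lies inside (or on
#' the boundary of) any tumor annotation polygon; otherwise it is non-tumor.
#' With an empty annotation set (e.g. an unannotated technical-failure slide)
#' the tile stays `"unlabeled"`.
#'
#' @param tile a [Tile-class].
#' @param polygons list of N x 2 polygon matrices (x, y pixel coordinates),
#'   each simple and implicitly closed.
#' @return The tile with its `label` slot set.
#' @export
labelTile <- function(tile, polygons) {
  stopifnot(is(tile, "Tile"))
  if (length(polygons) == 0L) {
    tile@label <- "unlabeled"
    return(tile)
  }
  lapply(polygons, checkPolygon)
  ctr <- tileCenter(tile)
  tile@label <- if (pointInAnyPolygon(ctr["x"], ctr["y"], polygons)) {
    "tumor"
  } else {
    "non-tumor"
  }
  tile
}

#' @rdname labelTile
#' @param tiles list of tiles.
#' @export
labelTiles <- function(tiles, polygons) {
  lapply(tiles, labelTile, polygons = polygons)
}

#' Tile manifest table
#'
#' @param tiles list of [Tile-class] objects.
#' @return data.frame with columns slide_id, i, j, x, y, label.
#' @export
tileManifest <- function(tiles) {
  data.frame(
    slide_id = vapply(tiles, slideId_tile, character(1)),
    i = vapply(tiles, function(t) t@i, integer(1)),
    j = vapply(tiles, function(t) t@j, integer(1)),
    x = vapply(tiles, function(t) t@x, integer(1)),
    y = vapply(tiles, function(t) t@y, integer(1)),
    label = vapply(tiles, tileLabel, character(1)),
    stringsAsFactors = FALSE
  )
}

slideId_tile <- function(t) t@slideId

#' Ground-truth cell table for one tile
#'
#' Extracts the planted cells whose nuclei fall inside a tile as a cell table
#' (see [cellTable()]) with tile-local pixel-index masks. The synthetic
#' generator keeps each nucleus inside a single tile, so no mask is split.
#'
#' @param truth a [GroundTruth-class].
#' @param tile a [Tile-class] from the same slide.
#' @return A cell table with one row per planted cell in the tile.
#' @export
tileCellTable <- function(truth, tile) {
  ts <- tileSize()
  sub <- instanceMask(truth)[(tile@y + 1L):(tile@y + ts),
                             (tile@x + 1L):(tile@x + ts), drop = FALSE]
  ids <- sort(unique(as.vector(sub)))
  ids <- ids[ids > 0L]
  if (length(ids) == 0L) return(cellTable())
  df <- cells(truth)
  masks <- lapply(ids, function(id) which(sub == id))
  cellTable(
    class = df$class[match(ids, df$cell)],
    confidence = rep(1, length(ids)),
    mask = masks
  )
}
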