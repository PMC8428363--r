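#' Read and write slides, annotations, and cell tables
#'
#' Plain-text/raster interchange: slides as PNG plus a JSON sidecar carrying
#' the physical pixel spacing, slide id and failure mode; polygon
#' annotations as GeoJSON in pixel coordinates (x right, y down, 0-based);
#' cell tables as JSON with run-length-encoded masks.
#'
#' @name slideIO
NULL

#' @rdname slideIO
#' @param slide a [SlideImage-class].
#' @param path PNG file path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
writeSlideImage <- function(slide, path) {
  stopifnot(is(slide, "SlideImage"))
  png::writePNG(slidePixels(slide), target = path)
  jsonlite::write_json(
    list(slide_id = slideId(slide), mpp = mpp(slide),
         failure_mode = failureMode(slide)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slideIO
#' @return `readSlideImage`: a [SlideImage-class].
#' @export
readSlideImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]
  meta <- list(slide_id = "slide", mpp = 0.227, failure_mode = "none")
  sc <- paste0(path, ".json")
  if (file.exists(sc)) meta <- utils::modifyList(meta, jsonlite::read_json(sc))
  new("SlideImage", image = img, mpp = meta$mpp, slideId = meta$slide_id,
      failureMode = meta$failure_mode)
}

#' @rdname slideIO
#' @param polygons list of N x 2 polygon matrices.
#' @export
writePolygonsGeoJSON <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    ring <- rbind(p, p[1, , drop = FALSE]) # GeoJSON rings are closed
    list(type = "Feature", properties = list(label = "tumor"),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(ring, 1, as.list,
                                                         simplify = FALSE)))))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slideIO
#' @return `readPolygonsGeoJSON`: list of N x 2 matrices (x, y), open rings.
#' @export
readPolygonsGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    colnames(m) <- c("x", "y")
    m
  })
}

#' @rdname slideIO
#' @param tbl a cell table (see [cellTable()]).
#' @export
writeCellTableJSON <- function(tbl, path) {
  recs <- lapply(seq_len(nrow(tbl)), function(i) {
    r <- list(class = tbl$class[i], confidence = tbl$confidence[i],
              rle = maskToRle(tbl$mask[[i]]))
    if (!is.null(tbl$tile)) r$tile <- tbl$tile[i]
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname slideIO
#' @return `readCellTableJSON`: a cell table.
#' @export
readCellTableJSON <- function(path) {
  recs <- jsonlite::read_json(path)
  if (length(recs) == 0L) return(cellTable())
  tiles <- vapply(recs, function(r) {
    if (is.null(r$tile)) NA_integer_ else as.integer(r$tile)
  }, integer(1))
  cellTable(
    class = vapply(recs, function(r) r$class, character(1)),
    confidence = vapply(recs, function(r) as.numeric(r$confidence), numeric(1)),
    mask = lapply(recs, function(r) rleToMask(unlist(r$rle))),
    tile = if (all(is.na(tiles))) NULL else tiles
  )
}

#' Annotation inventory of the development cohorts
#'
#' The tile and cell counts of the annotated material used to design the
#' tumor detector and the four-class cell classifier: per-subset tile counts
#' for the tumor detector (with tumor/non-tumor splits) and per-subset cell
#' counts for the PTEN classifier (with positive/negative splits). These
#' counts anchor the resource-accounting checks: the cell counts sum to
#' 77,777 annotated nuclei over 3060 annotated tiles.
#'
#' @return A list of three data.frames: `detector_tiles` (subset, n_tiles,
#'   n_tumor, n_nontumor), `classifier_tiles` (subset, n_tiles) and `cells`
#'   (subset, n_pos, n_neg).
#' @export
#' @examples
#' sum(with(annotationInventory()$cells, n_pos + n_neg))
annotationInventory <- function() {
  list(
    detector_tiles = data.frame(
      subset = c("train", "tune"),
      n_tiles = c(881418L, 332211L),
      n_tumor = c(241170L, 97587L),
      n_nontumor = c(640248L, 234624L),
      stringsAsFactors = FALSE
    ),
    classifier_tiles = data.frame(
      subset = c("train", "tune"),
      n_tiles = c(2160L, 900L),
      stringsAsFactors = FALSE
    ),
    cells = data.frame(
      subset = c("train", "tune"),
      n_pos = c(46434L, 17396L),
      n_neg = c(11146L, 2801L),
      stringsAsFactors = FALSE
    )
  )
}
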