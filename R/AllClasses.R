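#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges IntegerList
NULL

#' The four PTEN cell classes
#'
#' Every detected or annotated cell belongs to exactly one of four classes:
#' tumor or non-tumor crossed with PTEN-positive (cytoplasmic and/or nuclear
#' DAB staining present) or PTEN-negative (staining absent).
#'
#' @return Character vector of the four class labels, in canonical order.
#' @export
#' @examples
#' ptenClasses()
ptenClasses <- function() {
  c("tumor_pos", "tumor_neg", "nontumor_pos", "nontumor_neg")
}

#' SlideImage: an RGB slide raster with physical pixel spacing
#'
#' Container for a (possibly synthetic) IHC-stained slide. The pixel array is
#' indexed `image[y + 1, x + 1, channel]` with `x` rightwards and `y`
#' downwards, 0-based coordinates in all public interfaces, channel values in
#' `[0, 1]`.
#'
#' @slot image numeric array, height x width x 3, values in `[0, 1]`.
#' @slot mpp microns per pixel (scalar); the default synthesis resolution is
#'   0.227 um/px.
#' @slot slideId character identifier.
#' @slot failureMode one of `"none"`, `"low_antibody"`, `"no_antibody"`.
#' @exportClass SlideImage
setClass("SlideImage",
  representation(
    image = "array",
    mpp = "numeric",
    slideId = "character",
    failureMode = "character"
  ),
  prototype(mpp = 0.227, slideId = "slide", failureMode = "none")
)

setValidity("SlideImage", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) {
    return("image must be a height x width x 3 array")
  }
  if (length(object@mpp) != 1L || !is.finite(object@mpp) || object@mpp <= 0) {
    return("mpp must be a single positive number")
  }
  if (any(object@image < 0 | object@image > 1, na.rm = TRUE)) {
    return("image values must lie in [0, 1]")
  }
  if (!object@failureMode %in% c("none", "low_antibody", "no_antibody")) {
    return("failureMode must be one of none, low_antibody, no_antibody")
  }
  TRUE
})

#' GroundTruth: per-cell and per-region truth for a synthetic slide
#'
#' @slot polygons list of N x 2 matrices (columns x, y; pixel coordinates,
#'   0-based, y down) delimiting tumor regions. Polygons are closed implicitly.
#' @slot cells data.frame with one row per planted cell: `cell` (integer id,
#'   matching the instance mask), `class` (see [ptenClasses()]), `x`, `y`
#'   (centroid), and the generating ellipse parameters `a`, `b`, `theta`.
#' @slot instanceMask integer matrix, height x width; 0 is background,
#'   positive values are cell ids (nucleus pixels only).
#' @slot failure logical; `TRUE` for technical-failure slides (reduced or
#'   absent antibody staining).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    polygons = "list",
    cells = "data.frame",
    instanceMask = "matrix",
    failure = "logical"
  )
)

setValidity("GroundTruth", function(object) {
  if (nrow(object@cells) > 0) {
    need <- c("cell", "class", "x", "y")
    if (!all(need %in% names(object@cells))) {
      return("cells must contain columns cell, class, x, y")
    }
    if (!all(object@cells$class %in% ptenClasses())) {
      return("cell classes must be one of the four PTEN classes")
    }
    ids <- sort(unique(as.vector(object@instanceMask)))
    ids <- ids[ids > 0]
    if (!all(object@cells$cell %in% ids)) {
      return("every cell must have a non-empty instance mask")
    }
  }
  TRUE
})

#' Tile: one 800 x 800 partition unit of a slide
#'
#' Tiles live on a grid anchored at the slide origin; tile `(i, j)` covers the
#' half-open pixel region `[800 i, 800 i + 800) x [800 j, 800 j + 800)` and
#' its center is the pixel point `(800 i + 400, 800 j + 400)`.
#'
#' @slot slideId character.
#' @slot i,j integer grid indices (i along x, j along y; 0-based).
#' @slot x,y integer pixel origin of the tile (0-based).
#' @slot pixels 800 x 800 x 3 numeric array (`pixels[ty + 1, tx + 1, ]`).
#' @slot label one of `"tumor"`, `"non-tumor"`, `"unlabeled"`.
#' @exportClass Tile
setClass("Tile",
  representation(
    slideId = "character",
    i = "integer", j = "integer",
    x = "integer", y = "integer",
    pixels = "array",
    label = "character"
  ),
  prototype(label = "unlabeled")
)

setValidity("Tile", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[1] != tileSize() || d[2] != tileSize() || d[3] != 3L) {
    return(sprintf("pixels must be %d x %d x 3", tileSize(), tileSize()))
  }
  if (!object@label %in% c("tumor", "non-tumor", "unlabeled")) {
    return("label must be tumor, non-tumor or unlabeled")
  }
  TRUE
})

#' Side length of the tile grid, in pixels
#' @return The integer 800.
#' @export
tileSize <- function() 800L

#' TileClassifier: a fitted tumor-tile detector
#'
#' @slot backend backend identifier (`"lda"` reference backend or
#'   `"annotation"` oracle).
#' @slot threshold decision threshold on the tumor probability (default 0.5).
#' @slot fit backend-specific fitted state.
#' @slot seed integer seed recorded at training time.
#' @exportClass TileClassifier
setClass("TileClassifier",
  representation(
    backend = "character",
    threshold = "numeric",
    fit = "list",
    seed = "integer"
  ),
  prototype(backend = "lda", threshold = 0.5, seed = NA_integer_)
)

setValidity("TileClassifier", function(object) {
  if (length(object@threshold) != 1L || object@threshold < 0 || object@threshold > 1) {
    return("threshold must be a single value in [0, 1]")
  }
  TRUE
})

#' CellModel: a fitted cell detector / four-class classifier
#'
#' @slot backend `"segmentation"` (reference backend: stain unmixing,
#'   watershed nucleus segmentation, per-instance linear classifiers) or
#'   `"oracle"` (emits planted ground truth; for pipeline testing).
#' @slot fit backend-specific fitted state.
#' @slot seed integer seed recorded at training time.
#' @exportClass CellModel
setClass("CellModel",
  representation(
    backend = "character",
    fit = "list",
    seed = "integer"
  ),
  prototype(backend = "segmentation", seed = NA_integer_)
)

#' AnnotationRevision: result of one annotation-refinement round
#'
#' Model detections that do not overlap any original annotation (IoU below the
#' matching threshold against every annotation) are given reviewer-assigned
#' four-class labels and merged into the annotation set for a second training
#' round. The merged set always contains the original set.
#'
#' @slot original cell table of the original annotations (see [cellTable()]).
#' @slot unmatched cell table of the unmatched detections, with reviewer labels.
#' @slot merged cell table: original plus labeled unmatched detections.
#' @slot iouThreshold matching threshold used (boundary-inclusive: IoU equal
#'   to the threshold counts as matched).
#' @exportClass AnnotationRevision
setClass("AnnotationRevision",
  representation(
    original = "DataFrame",
    unmatched = "DataFrame",
    merged = "DataFrame",
    iouThreshold = "numeric"
  )
)

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "SlideImage '%s': %d x %d px, %.3f um/px, failure mode '%s'\n",
    object@slideId, d[2], d[1], object@mpp, object@failureMode
  ))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d tumor polygon(s), %d cell(s)%s\n",
    length(object@polygons), nrow(object@cells),
    if (isTRUE(object@failure)) " [technical-failure slide]" else ""
  ))
  if (nrow(object@cells) > 0) {
    print(table(factor(object@cells$class, levels = ptenClasses())))
  }
})

setMethod("show", "Tile", function(object) {
  cat(sprintf(
    "Tile (%d, %d) of '%s' at (%d, %d), label '%s'\n",
    object@i, object@j, object@slideId, object@x, object@y, object@label
  ))
})

setMethod("show", "TileClassifier", function(object) {
  cat(sprintf(
    "TileClassifier backend '%s', threshold %.2f, seed %s\n",
    object@backend, object@threshold, as.character(object@seed)
  ))
})

setMethod("show", "CellModel", function(object) {
  cat(sprintf("CellModel backend '%s', seed %s\n",
              object@backend, as.character(object@seed)))
})

setMethod("show", "AnnotationRevision", function(object) {
  cat(sprintf(
    "AnnotationRevision: %d original, %d unmatched (IoU < %.2f), %d merged\n",
    nrow(object@original), nrow(object@unmatched), object@iouThreshold,
    nrow(object@merged)
  ))
})

# --- accessors -------------------------------------------------------------

#' @describeIn SlideImage-class pixel array accessor
#' @param x object
#' @export
slidePixels <- function(x) x@image

#' @describeIn SlideImage-class microns-per-pixel accessor
#' @export
mpp <- function(x) x@mpp

#' @describeIn SlideImage-class slide identifier accessor
#' @export
slideId <- function(x) x@slideId

#' @describeIn SlideImage-class failure-mode accessor
#' @export
failureMode <- function(x) x@failureMode

#' @describeIn GroundTruth-class per-cell truth table accessor
#' @param x object
#' @export
cells <- function(x) x@cells

#' @describeIn GroundTruth-class tumor polygon list accessor
#' @export
tumorPolygons <- function(x) x@polygons

#' @describeIn GroundTruth-class instance-mask accessor
#' @export
instanceMask <- function(x) x@instanceMask

#' @describeIn GroundTruth-class technical-failure flag accessor
#' @export
isFailureSlide <- function(x) x@failure

#' @describeIn Tile-class tile label accessor
#' @param x object
#' @export
tileLabel <- function(x) x@label

#' @describeIn Tile-class tile pixel payload accessor
#' @export
tilePixels <- function(x) x@pixels

#' @describeIn Tile-class tile pixel origin, c(x, y), 0-based
#' @export
tileOrigin <- function(x) c(x = x@x, y = x@y)

#' @describeIn Tile-class tile center pixel point, c(x, y)
#' @export
tileCenter <- function(x) c(x = x@x + tileSize() / 2, y = x@y + tileSize() / 2)

#' Construct an empty cell table
#'
#' Detections and annotations share one representation: an
#' [S4Vectors::DataFrame] with a `class` column (one of [ptenClasses()]), a
#' `confidence` column in `[0, 1]`, and a `mask` column
#' ([IRanges::IntegerList]) of 1-based linear pixel indices into the 800 x 800
#' tile (column-major: index = 800 * x + y + 1 for 0-based tile coordinates).
#' An optional `tile` column scopes masks to tiles when several tiles are
#' pooled.
#'
#' @param class character vector of cell classes.
#' @param confidence numeric vector in `[0, 1]` (1 for annotations).
#' @param mask list (or `IntegerList`) of integer vectors of pixel indices.
#' @param tile optional integer vector of tile indices.
#' @return A `DataFrame` with zero or more rows.
#' @export
#' @examples
#' cellTable(class = "tumor_pos", confidence = 1, mask = list(1:10))
cellTable <- function(class = character(), confidence = numeric(),
                      mask = list(), tile = NULL) {
  stopifnot(all(class %in% ptenClasses()))
  n <- length(class)
  if (length(confidence) == 1L && n > 1L) confidence <- rep(confidence, n)
  if (any(lengths(mask) == 0L) && n > 0L) {
    stop("cell masks must be non-empty")
  }
  out <- S4Vectors::DataFrame(
    class = as.character(class),
    confidence = as.numeric(confidence),
    mask = IRanges::IntegerList(mask)
  )
  if (!is.null(tile)) out$tile <- as.integer(tile)
  out
}
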