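mkSlide <- function(w, h, seed = 1) {
  img <- array(stats::runif(w * h * 3), dim = c(h, w, 3))
  new("SlideImage", image = img, mpp = 0.227, slideId = "t",
      failureMode = "none")
}

test_that("partition counts and origins follow the drop-remainder grid", {
  set.seed(1)
  t6 <- partitionTiles(mkSlide(1600, 2400))
  expect_length(t6, 6L)
  org <- unique(t(vapply(t6, tileOrigin, c(x = 0, y = 0))))
  expect_setequal(paste(org[, "x"], org[, "y"]),
                  paste(rep(c(0, 800), 3), rep(c(0, 800, 1600), each = 2)))
  expect_length(partitionTiles(mkSlide(1000, 900)), 1L)
  expect_length(partitionTiles(mkSlide(799, 799)), 0L)
})

test_that("tiles partition the cropped image exactly", {
  set.seed(2)
  s <- mkSlide(1700, 900)
  tiles <- partitionTiles(s)
  expect_length(tiles, 2L)
  recon <- array(NA_real_, dim = c(800, 1600, 3))
  for (t in tiles) {
    recon[(t@y + 1):(t@y + 800), (t@x + 1):(t@x + 800), ] <- tilePixels(t)
  }
  expect_false(anyNA(recon))
  expect_identical(recon, slidePixels(s)[1:800, 1:1600, , drop = FALSE])
})

test_that("tile labels follow the center-in-polygon rule", {
  set.seed(3)
  tile <- partitionTiles(mkSlide(800, 800))[[1]]
  square <- cbind(x = c(0, 800, 800, 0), y = c(0, 0, 800, 800))
  expect_identical(tileLabel(labelTile(tile, list(square))), "tumor")
  # polygon covering most of the tile but with a slit excluding the center
  notch <- cbind(x = c(0, 800, 800, 395, 395, 800, 800, 0),
                 y = c(0, 0, 395, 395, 405, 405, 800, 800))
  expect_identical(tileLabel(labelTile(tile, list(notch))), "non-tumor")
  # center exactly on an edge counts as tumor (boundary-inclusive)
  half <- cbind(x = c(0, 400, 400, 0), y = c(0, 0, 800, 800))
  expect_identical(tileLabel(labelTile(tile, list(half))), "tumor")
  # no annotations: unlabeled
  expect_identical(tileLabel(labelTile(tile, list())), "unlabeled")
})

test_that("self-intersecting polygons are rejected", {
  set.seed(4)
  tile <- partitionTiles(mkSlide(800, 800))[[1]]
  bowtie <- cbind(x = c(0, 800, 0, 800), y = c(0, 800, 800, 0))
  expect_error(labelTile(tile, list(bowtie)), "self-intersecting")
})

test_that("labels are invariant to vertex order and joint translation", {
  set.seed(5)
  s <- generateSlide(slideSpec(widthPx = 1600, heightPx = 1600,
                               nTumorRegions = 2, seed = 13))
  tiles <- partitionTiles(s$slide)
  polys <- tumorPolygons(s$truth)
  lab0 <- vapply(labelTiles(tiles, polys), tileLabel, character(1))
  rev0 <- lapply(polys, function(p) p[rev(seq_len(nrow(p))), , drop = FALSE])
  expect_identical(vapply(labelTiles(tiles, rev0), tileLabel, character(1)),
                   lab0)
  # translate polygons and tile centers together by one grid step
  shifted <- lapply(polys, function(p) sweep(p, 2, c(800, 800), "+"))
  tilesShift <- lapply(tiles, function(t) {
    t@x <- t@x + 800L; t@y <- t@y + 800L; t
  })
  expect_identical(
    vapply(labelTiles(tilesShift, shifted), tileLabel, character(1)), lab0)
})

test_that("boundary-inclusive containment matches a ray-casting oracle off the boundary", {
  set.seed(6)
  poly <- cbind(x = c(10, 90, 95, 50, 5), y = c(5, 10, 80, 95, 70))
  px <- runif(300, 0, 100); py <- runif(300, 0, 100)
  # sp-free reference: even-odd rule evaluated with a different ray direction
  oracle <- function(x, y) {
    n <- nrow(poly); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((poly[i, 2] > y) != (poly[j, 2] > y) &&
          x < (poly[j, 1] - poly[i, 1]) * (y - poly[i, 2]) /
            (poly[j, 2] - poly[i, 2]) + poly[i, 1]) {
        inside <- !inside
      }
      j <- i
    }
    inside
  }
  got <- PTENpipe:::pointInPolygon(px, py, poly)
  want <- mapply(oracle, px, py)
  expect_identical(unname(got), unname(want))
  # vertices and edge midpoints are inside under the inclusive rule
  mids <- (poly + poly[c(2:5, 1), ]) / 2
  expect_true(all(PTENpipe:::pointInPolygon(poly[, 1], poly[, 2], poly)))
  expect_true(all(PTENpipe:::pointInPolygon(mids[, 1], mids[, 2], poly)))
})

test_that("polygon GeoJSON round-trips in pixel coordinates", {
  polys <- list(cbind(x = c(0, 10, 10, 0), y = c(0, 0, 12, 12)),
                cbind(x = c(3.5, 8, 5), y = c(2, 4, 9.25)))
  f <- tempfile(fileext = ".geojson")
  on.exit(unlink(f))
  writePolygonsGeoJSON(polys, f)
  back <- readPolygonsGeoJSON(f)
  expect_equal(back, polys, ignore_attr = TRUE)
})
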