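test_that("oracle backend emits the planted ground truth", {
  fx <- fxTilePair(51, tumor = TRUE, posfrac = 0.6)
  mod <- oracleCellModel(setNames(list(fx$truth), fx$tile@slideId))
  det <- detectCells(mod, fx$tile)
  ref <- tileCellTable(fx$truth, fx$tile)
  expect_identical(det$class, ref$class)
  expect_identical(as.list(det$mask), as.list(ref$mask))
  expect_true(all(det$confidence == 1))
  expect_equal(meanAveragePrecision(det, ref)$mAP, 1)
  # unknown slide is an error, not silence
  other <- fxTilePair(52)$tile
  expect_error(detectCells(mod, other), "no truth")
})

test_that("a blank tile yields an empty detection table", {
  blank <- new("SlideImage", image = array(1, c(800, 800, 3)), mpp = 0.227,
               slideId = "blank", failureMode = "none")
  tile <- partitionTiles(blank)[[1]]
  det <- detectCells(fxCellModel(), tile)
  expect_identical(nrow(det), 0L)
})

test_that("non-maximum suppression removes duplicate proposals", {
  m <- list(1:30, 1:30, 2001:2030)
  det <- cellTable(class = c("tumor_pos", "tumor_pos", "tumor_neg"),
                   confidence = c(0.7, 0.9, 0.5), mask = m)
  kept <- suppressDetections(det)
  expect_identical(nrow(kept), 2L)
  # the higher-confidence duplicate survives
  expect_identical(kept$confidence, c(0.9, 0.5))
  # below-threshold overlap is not suppressed
  part <- cellTable(class = c("tumor_pos", "tumor_pos"),
                    confidence = c(0.9, 0.8), mask = list(1:30, 21:50))
  expect_identical(nrow(suppressDetections(part)), 2L)
})

test_that("detections match the free truth instance of highest IoU", {
  truths <- list(1:30, 16:45)
  # detection overlaps both truths; the second has higher IoU
  got <- PTENpipe:::matchDetections(list(20:49), 1, truths, 0.5)
  expect_identical(got, 2L)
  # IoU exactly at the threshold counts as a match: |A|=|B|=30, overlap 20
  expect_identical(PTENpipe:::matchDetections(list(11:40), 1, list(1:30), 0.5),
                   1L)
  expect_identical(
    PTENpipe:::matchDetections(list(11:40), 1, list(1:30), 0.5 + 1e-9),
    NA_integer_)
  # each truth consumed once: two identical detections, one truth
  two <- PTENpipe:::matchDetections(list(1:30, 1:30), c(0.9, 0.8),
                                    list(1:30), 0.5)
  expect_identical(two, c(1L, NA_integer_))
})

test_that("average precision matches hand-computed values", {
  tru <- cellTable(class = rep("tumor_pos", 3), confidence = rep(1, 3),
                   mask = list(1:10, 101:110, 201:210))
  det <- cellTable(
    class = rep("tumor_pos", 4),
    confidence = c(0.9, 0.8, 0.7, 0.6),
    mask = list(1:10, 301:310, 101:110, 205:214)
  )
  # ranked outcomes TP, FP, TP, FP against 3 truths:
  # envelope precision 1, 2/3, 2/3, 1/2 over recall steps 1/3, 0, 1/3, 0
  expect_equal(meanAveragePrecision(det, tru)$mAP, 1 / 3 + 2 / 9)
  # duplicate of a matched truth is a false positive that AP ignores when
  # it is ranked below the hit: single truth, perfect hit first
  tru1 <- cellTable(class = "tumor_neg", confidence = 1, mask = list(1:10))
  dup <- cellTable(class = rep("tumor_neg", 2), confidence = c(0.9, 0.8),
                   mask = list(1:10, 1:10))
  expect_equal(meanAveragePrecision(dup, tru1)$mAP, 1)
  # wrong-class detections never match
  wrong <- cellTable(class = "nontumor_pos", confidence = 1, mask = list(1:10))
  expect_equal(meanAveragePrecision(wrong, tru1)$mAP, 0)
  # no detections for a present class scores zero; empty truth is an error
  expect_equal(meanAveragePrecision(cellTable(), tru1)$mAP, 0)
  expect_error(meanAveragePrecision(det, cellTable()), "non-empty")
})

test_that("mAP averages only over classes present in the truth", {
  tru <- cellTable(class = c("tumor_pos", "tumor_neg"),
                   confidence = c(1, 1), mask = list(1:10, 101:110))
  det <- cellTable(class = c("tumor_pos", "nontumor_neg"),
                   confidence = c(1, 1), mask = list(1:10, 201:210))
  r <- meanAveragePrecision(det, tru)
  expect_setequal(names(r$perClass), c("tumor_pos", "tumor_neg"))
  expect_equal(unname(r$perClass["tumor_pos"]), 1)
  expect_equal(unname(r$perClass["tumor_neg"]), 0)
  expect_equal(r$mAP, 0.5)
})

test_that("the reference backend detects and classifies held-out cells", {
  fx <- fxMixedPair(61)
  det <- detectCells(fxCellModel(), fx$tile)
  tru <- tileCellTable(fx$truth, fx$tile)
  r <- meanAveragePrecision(det, tru)
  expect_gt(r$mAP, 0.5)
  # determinism
  det2 <- detectCells(fxCellModel(), fx$tile)
  expect_identical(det$class, det2$class)
  expect_identical(det$confidence, det2$confidence)
})

test_that("refinement flags dropped annotations and the merge restores them", {
  fx <- fxMixedPair(62)
  tiles <- list(fx$tile)
  full <- tileCellTable(fx$truth, fx$tile)
  mod <- oracleCellModel(setNames(list(fx$truth), fx$tile@slideId))
  reviewer <- groundTruthReviewer(fx$truth, tiles)
  # complete annotations: nothing is unmatched
  rev0 <- refineAnnotations(mod, tiles, list(full), reviewer)
  expect_identical(nrow(rev0@unmatched), 0L)
  expect_identical(nrow(rev0@merged), nrow(full))
  # drop a third of the annotations: exactly those come back, with the
  # planted labels, and the merged set equals the full set in content
  drop <- seq(1, nrow(full), by = 3)
  partial <- full[-drop, , drop = FALSE]
  rev1 <- refineAnnotations(mod, tiles, list(partial), reviewer)
  expect_identical(nrow(rev1@unmatched), length(drop))
  expect_identical(rev1@unmatched$class, full$class[drop])
  expect_identical(nrow(rev1@merged), nrow(full))
  expect_gte(nrow(rev1@merged), nrow(partial))
})

test_that("refinement rejects reviewer labels outside the class set", {
  fx <- fxMixedPair(62)
  full <- tileCellTable(fx$truth, fx$tile)
  mod <- oracleCellModel(setNames(list(fx$truth), fx$tile@slideId))
  bad <- function(tileIdx, mask) "stromal"
  expect_error(
    refineAnnotations(mod, list(fx$tile), list(full[-1, , drop = FALSE]), bad),
    "reviewer label")
})
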