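test_that("slide score is the tumor-positive fraction of tumor cells", {
  cl <- rep(c("tumor_pos", "tumor_neg", "nontumor_pos", "nontumor_neg"),
            c(80, 20, 300, 200))
  s <- slidePtenScore(cl)
  expect_equal(s$score, 0.80)
  expect_identical(s$n_tumor_pos, 80L)
  expect_identical(s$n_tumor_neg, 20L)
  # non-tumor cells never enter numerator or denominator
  expect_equal(slidePtenScore(rep(c("tumor_pos", "tumor_neg"), c(80, 20)))$score,
               0.80)
  # works identically on a cell table
  tbl <- cellTable(class = cl, confidence = 1,
                   mask = lapply(seq_along(cl), function(i) i))
  expect_equal(slidePtenScore(tbl)$score, 0.80)
  expect_error(slidePtenScore(c("tumor_pos", "lymphocyte")))
})

test_that("a slide with no tumor cells has an undefined score", {
  s <- slidePtenScore(rep("nontumor_neg", 50))
  expect_true(is.na(s$score))
  expect_true(is.na(slidePtenScore(character())$score))
  expect_output(print(s), "undefined")
})

test_that("patient score is the unweighted mean of defined slide scores", {
  expect_equal(patientPtenScore(c(0.2, 0.4, 0.9)), 0.5)
  # undefined slides are excluded, not zero-filled
  expect_equal(patientPtenScore(c(0.7, NA, 0.9)), 0.8)
  expect_true(is.na(patientPtenScore(c(NA_real_, NA_real_))))
  # unweighted: a patient with slides (1.0) and (0.0) scores 0.5 regardless
  # of how many cells each slide carried
  lst <- list(slidePtenScore(rep("tumor_pos", 1000)),
              slidePtenScore(rep("tumor_neg", 10)))
  expect_equal(patientPtenScore(lst), 0.5)
  expect_error(patientPtenScore(c(0.5, 1.2)))
})

test_that("dichotomization at 0.5 is strict", {
  expect_identical(dichotomizePten(c(0.49, 0.5, 1.0)),
                   c("PTEN-low", "PTEN-high", "PTEN-high"))
  expect_identical(dichotomizePten(0), "PTEN-low")
  expect_identical(dichotomizePten(NA_real_), NA_character_)
  expect_identical(dichotomizePten(0.6, threshold = 0.7), "PTEN-low")
})

test_that("ploidy dichotomization groups tetraploid with aneuploid", {
  expect_identical(dichotomizePloidy(c("diploid", "tetraploid", "aneuploid")),
                   c("diploid", "non-diploid", "non-diploid"))
  expect_identical(dichotomizePloidy(NA_character_), NA_character_)
  expect_error(dichotomizePloidy("haploid"), "unknown ploidy")
})

test_that("combined marker counts adverse statuses", {
  expect_identical(combinedMarker("PTEN-high", "diploid"), "both-favorable")
  expect_identical(combinedMarker("PTEN-low", "diploid"), "one-adverse")
  expect_identical(combinedMarker("PTEN-high", "tetraploid"), "one-adverse")
  expect_identical(combinedMarker("PTEN-low", "aneuploid"), "both-adverse")
  # dichotomized ploidy accepted too
  expect_identical(combinedMarker("PTEN-low", "non-diploid"), "both-adverse")
  expect_identical(combinedMarker(NA, "diploid"), NA_character_)
  expect_identical(combinedMarker("PTEN-low", NA), NA_character_)
  expect_error(combinedMarker("low", "diploid"))
})

test_that("CAPRA-S integration adds one point per adverse marker", {
  r <- capraSIntegrate(5, "PTEN-low", "non-diploid")
  expect_identical(r$integrated, 7L)
  expect_identical(r$risk_group, "High")
  expect_identical(capraSIntegrate(2, "PTEN-high", "diploid")$risk_group,
                   "Low")
  expect_identical(capraSIntegrate(2, "PTEN-low", "diploid")$integrated, 3L)
  expect_identical(capraSIntegrate(3, "PTEN-high", "diploid")$risk_group,
                   "Intermediate")
  # missing marker status voids the integrated score
  r2 <- capraSIntegrate(c(4, 4), c("PTEN-low", NA), c("diploid", "diploid"))
  expect_identical(r2$integrated, c(5L, NA))
  expect_identical(r2$risk_group, c("Intermediate", NA))
  expect_error(capraSIntegrate(-1, "PTEN-low", "diploid"), "non-negative")
  expect_error(capraSIntegrate(2.5, "PTEN-low", "diploid"), "integer")
})

test_that("risk group boundaries are 0-2, 3-5, >= 6", {
  expect_identical(capraRiskGroup(0:7),
                   c("Low", "Low", "Low", "Intermediate", "Intermediate",
                     "Intermediate", "High", "High"))
})

test_that("integrated score is monotone in the marker statuses", {
  for (b in 0:8) {
    fav <- capraSIntegrate(b, "PTEN-high", "diploid")$integrated
    one <- capraSIntegrate(b, "PTEN-low", "diploid")$integrated
    both <- capraSIntegrate(b, "PTEN-low", "non-diploid")$integrated
    expect_true(fav <= one && one <= both)
    expect_identical(both - fav, 2L)
  }
})

test_that("slide score equals the planted score on the generator output", {
  fx <- fxTilePair(71, tumor = TRUE, posfrac = 0.35)
  tbl <- tileCellTable(fx$truth, fx$tile)
  got <- slidePtenScore(tbl)$score
  expect_equal(got, plantedScore(fx$truth))
})

test_that("score partition property: counts over disjoint tiles pool", {
  s <- generateSlide(slideSpec(widthPx = 1600, heightPx = 800,
                               nTumorRegions = 1, tumorRegionCover = "full",
                               positiveFraction = 0.6, seed = 19))
  tiles <- partitionTiles(s$slide)
  pooled <- unlist(lapply(tiles, function(t)
    tileCellTable(s$truth, t)$class))
  whole <- cells(s$truth)$class
  expect_identical(sort(pooled), sort(whole))
  expect_equal(slidePtenScore(pooled)$score, plantedScore(s$truth))
})
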