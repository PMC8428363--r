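#' Slide-level PTEN score from cell detections
#'
#' The PTEN score of a whole-slide image is the ratio of tumor PTEN-positive
#' cells to all tumor cells (positive plus negative). Non-tumor cells are
#' excluded from both numerator and denominator. When a slide yields no tumor
#' cells the score is undefined (`NA`), a representable state rather than an
#' error: such slides are dropped from the patient mean.
#'
#' @param detections a cell table (see [cellTable()]) pooled over the slide's
#'   tumor tiles, or a character vector of class labels.
#' @return A list of class `"SlideScore"` with the four class counts and
#'   `score` (`NA` when no tumor cells).
#' @export
#' @examples
#' slidePtenScore(rep(c("tumor_pos", "tumor_neg"), c(80, 20)))$score
slidePtenScore <- function(detections) {
  cl <- if (is.character(detections)) detections else detections$class
  stopifnot(all(cl %in% ptenClasses()))
  counts <- c(
    n_tumor_pos = sum(cl == "tumor_pos"),
    n_tumor_neg = sum(cl == "tumor_neg"),
    n_nontumor_pos = sum(cl == "nontumor_pos"),
    n_nontumor_neg = sum(cl == "nontumor_neg")
  )
  denom <- counts[["n_tumor_pos"]] + counts[["n_tumor_neg"]]
  score <- if (denom > 0) counts[["n_tumor_pos"]] / denom else NA_real_
  structure(c(as.list(counts), list(score = score)), class = "SlideScore")
}

#' @export
print.SlideScore <- function(x, ...) {
  cat(sprintf(
    "SlideScore: %d tumor+ / %d tumor- (non-tumor: %d+ %d-), score %s\n",
    x$n_tumor_pos, x$n_tumor_neg, x$n_nontumor_pos, x$n_nontumor_neg,
    if (is.na(x$score)) "undefined" else sprintf("%.4f", x$score)
  ))
  invisible(x)
}

#' Patient-level PTEN score
#'
#' The unweighted arithmetic mean of a patient's defined slide scores;
#' slides with undefined score are excluded. When every slide is undefined
#' the patient score is missing (`NA`), which propagates as a missing status
#' downstream.
#'
#' @param slideScores numeric vector of slide scores (may contain `NA`), or a
#'   list of `"SlideScore"` objects.
#' @return A single number in `[0, 1]`, or `NA`.
#' @export
#' @examples
#' patientPtenScore(c(0.2, 0.4, 0.9))
#' patientPtenScore(c(0.7, NA, 0.9))
patientPtenScore <- function(slideScores) {
  if (is.list(slideScores) && !is.numeric(slideScores)) {
    slideScores <- vapply(slideScores, function(s) s$score, numeric(1))
  }
  stopifnot(all(is.na(slideScores) | (slideScores >= 0 & slideScores <= 1)))
  if (all(is.na(slideScores))) return(NA_real_)
  mean(slideScores, na.rm = TRUE)
}

#' Dichotomize a PTEN score
#'
#' PTEN-low if and only if the score is strictly below the threshold;
#' a score exactly at the threshold is PTEN-high (the 50% convention:
#' PTEN-low < 50%, PTEN-high >= 50%). Missing scores give missing status.
#'
#' @param score numeric vector of scores in `[0, 1]` (NAs allowed).
#' @param threshold dichotomization threshold, default 0.5.
#' @return Character vector: `"PTEN-low"`, `"PTEN-high"`, or `NA`.
#' @export
#' @examples
#' dichotomizePten(c(0.49, 0.5, 1.0))
dichotomizePten <- function(score, threshold = 0.5) {
  stopifnot(all(is.na(score) | (score >= 0 & score <= 1)))
  ifelse(is.na(score), NA_character_,
         ifelse(score < threshold, "PTEN-low", "PTEN-high"))
}

#' Dichotomize a DNA ploidy category
#'
#' Non-diploid comprises tetraploid and aneuploid tumors.
#'
#' @param category character vector: `"diploid"`, `"tetraploid"`,
#'   `"aneuploid"` (NAs allowed).
#' @return Character vector: `"diploid"`, `"non-diploid"`, or `NA`.
#' @export
dichotomizePloidy <- function(category) {
  ok <- is.na(category) | category %in% c("diploid", "tetraploid", "aneuploid")
  if (!all(ok)) stop("unknown ploidy category: ",
                     paste(unique(category[!ok]), collapse = ", "))
  ifelse(is.na(category), NA_character_,
         ifelse(category == "diploid", "diploid", "non-diploid"))
}

#' Combined PTEN + ploidy prognostic marker
#'
#' The three-level ordinal marker counts adverse statuses: `both-favorable`
#' (PTEN-high and diploid), `one-adverse` (either PTEN-low or non-diploid),
#' `both-adverse` (PTEN-low and non-diploid). Missing input gives missing
#' output.
#'
#' @param ptenStatus `"PTEN-low"` / `"PTEN-high"` vector.
#' @param ploidy ploidy category (`"diploid"`, `"tetraploid"`, `"aneuploid"`)
#'   or dichotomized status (`"diploid"` / `"non-diploid"`).
#' @return Character vector of the three levels, or `NA`.
#' @export
#' @examples
#' combinedMarker("PTEN-low", "tetraploid")
combinedMarker <- function(ptenStatus, ploidy) {
  stopifnot(all(is.na(ptenStatus) | ptenStatus %in% c("PTEN-low", "PTEN-high")))
  ploidyStatus <- ifelse(ploidy %in% c("tetraploid", "aneuploid", "non-diploid"),
                         "non-diploid",
                         ifelse(ploidy %in% "diploid", "diploid", NA))
  nAdverse <- (ptenStatus == "PTEN-low") + (ploidyStatus == "non-diploid")
  out <- c("both-favorable", "one-adverse", "both-adverse")[nAdverse + 1L]
  out[is.na(ptenStatus) | is.na(ploidyStatus)] <- NA_character_
  out
}

#' Integrate PTEN and ploidy status into the CAPRA-S score
#'
#' Adds 1 point to the base CAPRA-S score if PTEN-low and 1 point if
#' non-diploid, and assigns the risk group: Low (0-2), Intermediate (3-5),
#' High (>= 6).
#'
#' @param base integer vector of base CAPRA-S scores (>= 0).
#' @param ptenStatus `"PTEN-low"` / `"PTEN-high"`.
#' @param ploidyStatus `"diploid"` / `"non-diploid"` (ploidy categories also
#'   accepted).
#' @return data.frame with columns `base`, `integrated`, `risk_group`.
#' @export
#' @examples
#' capraSIntegrate(5, "PTEN-low", "non-diploid")
capraSIntegrate <- function(base, ptenStatus, ploidyStatus) {
  if (any(!is.na(base) & (base < 0 | base != floor(base)))) {
    stop("base CAPRA-S score must be a non-negative integer")
  }
  ploidyStatus <- dichotomizePloidyStatus(ploidyStatus)
  integrated <- base +
    ifelse(!is.na(ptenStatus) & ptenStatus == "PTEN-low", 1L, 0L) +
    ifelse(!is.na(ploidyStatus) & ploidyStatus == "non-diploid", 1L, 0L)
  integrated[is.na(ptenStatus) | is.na(ploidyStatus) | is.na(base)] <- NA
  integrated <- as.integer(integrated)
  data.frame(
    base = base,
    integrated = integrated,
    risk_group = capraRiskGroup(integrated),
    stringsAsFactors = FALSE
  )
}

dichotomizePloidyStatus <- function(x) {
  ifelse(x %in% c("tetraploid", "aneuploid", "non-diploid"), "non-diploid",
         ifelse(x %in% "diploid", "diploid", NA))
}

#' CAPRA-S risk group from a score
#'
#' @param score integer CAPRA-S score vector.
#' @return `"Low"` (0-2), `"Intermediate"` (3-5), `"High"` (>= 6), `NA` for
#'   missing scores.
#' @export
capraRiskGroup <- function(score) {
  ifelse(is.na(score), NA_character_,
         ifelse(score <= 2, "Low",
                ifelse(score <= 5, "Intermediate", "High")))
}
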