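#' Cohort exclusion rules
#'
#' The standard roster-assembly filters: each rule reads a logical flag
#' column of the cohort table and excludes the rows where it is `TRUE`.
#'
#' @return Named list of predicate functions(data.frame) -> logical vector.
#' @export
defaultExclusionRules <- function() {
  ids <- c("missing_consent", "short_followup", "no_tumor_material",
           "preoperative_therapy", "postoperative_death", "lost_followup")
  rules <- lapply(ids, function(id) {
    force(id)
    function(df) {
      if (!id %in% names(df)) rep(FALSE, nrow(df)) else isTRUE_vec(df[[id]])
    }
  })
  names(rules) <- ids
  rules
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Apply exclusion rules to a cohort roster
#'
#' Splits a roster into eligible patients (triggering no rule) and excluded
#' patients, with a per-rule count report. A patient triggering several rules
#' is excluded once but counted under each rule.
#'
#' @param cohort data.frame, one row per patient, carrying the flag columns
#'   the rules read.
#' @param rules named list of rules; names must come from
#'   [defaultExclusionRules()].
#' @return A list: `eligible` (data.frame), `excluded` (data.frame with a
#'   `rules_triggered` column), `report` (data.frame rule, n).
#' @export
#' @examples
#' roster <- data.frame(patient = 1:5, missing_consent = c(TRUE, rep(FALSE, 4)))
#' applyExclusions(roster)$report
applyExclusions <- function(cohort, rules = defaultExclusionRules()) {
  known <- names(defaultExclusionRules())
  if (is.null(names(rules)) || !all(names(rules) %in% known)) {
    stop("unknown rule id: ",
         paste(setdiff(names(rules), known), collapse = ", "))
  }
  trig <- vapply(rules, function(r) r(cohort), logical(nrow(cohort)))
  if (nrow(cohort) == 1L) trig <- matrix(trig, nrow = 1L,
                                         dimnames = list(NULL, names(rules)))
  excludedRow <- apply(trig, 1L, any)
  report <- data.frame(rule = names(rules), n = colSums(trig),
                       row.names = NULL, stringsAsFactors = FALSE)
  excluded <- cohort[excludedRow, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$rules_triggered <- apply(
      trig[excludedRow, , drop = FALSE], 1L,
      function(r) paste(names(rules)[r], collapse = ";"))
  }
  list(eligible = cohort[!excludedRow, , drop = FALSE],
       excluded = excluded, report = report)
}

#' Configure a pipeline run
#'
#' @param slides optional named list (by slide id) of `list(slide, truth)`
#'   pairs as returned by [generateSlide()].
#' @param slidePatients named integer/character vector mapping slide id to
#'   patient id.
#' @param cellModel a fitted [CellModel-class] (reference backend or
#'   [oracleCellModel()]).
#' @param tumorDetector `"annotation"` (label tiles from the ground-truth
#'   polygons) or a fitted [TileClassifier-class].
#' @param cohort optional cohort list from [generateCohort()] (or a list
#'   with `patients` and `psa` data.frames).
#' @param ptenThreshold dichotomization threshold for PTEN-low (default 0.5).
#' @param B bootstrap replicates for the concordance/AUC intervals.
#' @param seed integer master seed, recorded in the results.
#' @return A list of class `"RunConfig"`.
#' @export
pipelineConfig <- function(slides = NULL, slidePatients = NULL,
                           cellModel = NULL, tumorDetector = "annotation",
                           cohort = NULL, ptenThreshold = 0.5,
                           B = 2000L, seed = 1L) {
  if (!is.null(slides)) {
    stopifnot(!is.null(names(slides)), !is.null(slidePatients))
    stopifnot(all(names(slides) %in% names(slidePatients)))
    if (is.null(cellModel)) stop("a cell model is required to score slides")
  }
  structure(list(slides = slides, slidePatients = slidePatients,
                 cellModel = cellModel, tumorDetector = tumorDetector,
                 cohort = cohort, ptenThreshold = ptenThreshold,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the full scoring and statistics pipeline
#'
#' Orchestrates slide scoring (tiling, tumor-tile selection, cell detection,
#' PTEN score), patient aggregation and dichotomization, combined-marker and
#' CAPRA-S integration, and the prognostic statistics on the cohort. All
#' stochastic stages derive their seeds from the config seed, so re-running
#' the same config reproduces the results exactly. Every input slide appears
#' exactly once in the slide table with a status.
#'
#' @param config a [pipelineConfig()].
#' @return A list of class `"PipelineResult"` with elements `slides`
#'   (per-slide scores and statuses), `patients` (per-patient markers),
#'   `stats` (survival statistics; `NULL` without a cohort), and `config`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  slideTab <- NULL
  if (!is.null(config$slides)) {
    rows <- lapply(names(config$slides), function(sid) {
      pair <- config$slides[[sid]]
      tiles <- partitionTiles(pair$slide)
      tiles <- if (identical(config$tumorDetector, "annotation")) {
        labelTiles(tiles, tumorPolygons(pair$truth))
      } else {
        lapply(tiles, function(t) {
          t@label <- classifyTile(config$tumorDetector, t)
          t
        })
      }
      tumorTiles <- Filter(function(t) tileLabel(t) == "tumor", tiles)
      cls <- unlist(lapply(tumorTiles, function(t) {
        detectCells(config$cellModel, t)$class
      }))
      if (is.null(cls)) cls <- character()
      sc <- slidePtenScore(cls)
      data.frame(
        slide_id = sid,
        patient = unname(config$slidePatients[sid]),
        n_tiles = length(tiles), n_tumor_tiles = length(tumorTiles),
        n_tumor_pos = sc$n_tumor_pos, n_tumor_neg = sc$n_tumor_neg,
        n_nontumor_pos = sc$n_nontumor_pos,
        n_nontumor_neg = sc$n_nontumor_neg,
        score = sc$score,
        status = if (isFailureSlide(pair$truth)) {
          if (is.na(sc$score)) "failed" else "scored"
        } else if (is.na(sc$score)) "undefined" else "scored",
        stringsAsFactors = FALSE
      )
    })
    slideTab <- do.call(rbind, rows)
  }

  patientTab <- NULL
  if (!is.null(config$cohort)) {
    patientTab <- config$cohort$patients
  }
  if (!is.null(slideTab)) {
    agg <- stats::aggregate(score ~ patient, data = slideTab,
                            FUN = patientPtenScore, na.action = stats::na.pass)
    names(agg)[2] <- "pipeline_score"
    cnt <- table(slideTab$patient)
    nsl <- data.frame(patient = type.convert(names(cnt), as.is = TRUE),
                      n_slides = as.integer(cnt))
    agg <- merge(agg, nsl, by = "patient", all.x = TRUE)
    patientTab <- if (is.null(patientTab)) {
      agg
    } else {
      merge(patientTab, agg, by = "patient", all.x = TRUE)
    }
  }
  if (!is.null(patientTab)) {
    score <- patientTab$pipeline_score
    if (is.null(score)) score <- rep(NA_real_, nrow(patientTab))
    if (!is.null(patientTab$auto_score)) {
      fill <- is.na(score) & !is.na(patientTab$auto_score)
      score[fill] <- patientTab$auto_score[fill]
    }
    patientTab$score <- score
    patientTab$pten_status <- dichotomizePten(score, config$ptenThreshold)
    if (!is.null(patientTab$ploidy)) {
      patientTab$ploidy_status <- dichotomizePloidy(patientTab$ploidy)
      patientTab$combined <- combinedMarker(patientTab$pten_status,
                                            patientTab$ploidy)
    } else {
      patientTab$ploidy_status <- NA_character_
      patientTab$combined <- NA_character_
    }
    if (!is.null(patientTab$capra_s)) {
      cap <- capraSIntegrate(patientTab$capra_s, patientTab$pten_status,
                             patientTab$ploidy_status)
      patientTab$capra_s_integrated <- cap$integrated
      patientTab$risk_group <- capraRiskGroup(patientTab$capra_s)
      patientTab$risk_group_integrated <- cap$risk_group
    }
  }

  statsOut <- NULL
  if (!is.null(config$cohort) && nrow(config$cohort$psa) > 0L) {
    statsOut <- pipelineStats(patientTab, config$cohort$psa,
                              B = config$B, seed = config$seed)
  }
  structure(list(slides = slideTab, patients = patientTab, stats = statsOut,
                 config = config),
            class = "PipelineResult")
}

# Survival statistics stage: BCR endpoint, KM/log-rank/Cox on PTEN status
# and the combined marker, concordance, AUC vs manual status, Pearson r.
pipelineStats <- function(patients, psa, B = 2000L, seed = 1L) {
  outc <- deriveBcrCohort(psa)
  d <- merge(patients, outc, by = "patient")
  out <- list(outcomes = outc)
  ok <- !is.na(d$pten_status)
  if (sum(d$event[ok]) >= 2 && length(unique(d$pten_status[ok])) == 2L) {
    ds <- d[ok, ]
    ds$pten_status <- factor(ds$pten_status, c("PTEN-high", "PTEN-low"))
    out$km_pten <- kmCurve(ds$time, ds$event, ds$pten_status)
    out$logrank_pten <- logrankTest(ds$time, ds$event, ds$pten_status)
    out$cox_pten <- coxFit(ds$time, ds$event,
                           data.frame(pten_status = ds$pten_status))
    out$cindex_pten <- harrellCindex(
      ds$time, ds$event, as.integer(ds$pten_status == "PTEN-low"),
      B = B, seed = seed)
  }
  okc <- !is.na(d$combined)
  if (any(okc) && length(unique(d$combined[okc])) == 3L) {
    dc <- d[okc, ]
    dc$combined <- factor(dc$combined,
                          c("both-favorable", "one-adverse", "both-adverse"))
    out$logrank_combined <- logrankTest(dc$time, dc$event, dc$combined)
    out$cox_combined <- coxFit(dc$time, dc$event,
                               data.frame(combined = dc$combined))
  }
  if (!is.null(d$manual_score) && !is.null(d$score)) {
    okm <- !is.na(d$manual_score) & !is.na(d$score)
    manualStatus <- dichotomizePten(d$manual_score[okm])
    if (length(unique(manualStatus)) == 2L) {
      out$auc_auto_vs_manual <- rocAuc(manualStatus == "PTEN-low",
                                       -d$score[okm], B = B, seed = seed + 1L)
    }
    if (sum(okm) >= 3L) {
      out$pearson_auto_manual <- pearsonR(d$score[okm], d$manual_score[okm])
    }
  }
  out
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  if (!is.null(x$slides)) {
    cat(sprintf("  slides: %d (%s)\n", nrow(x$slides),
                paste(sprintf("%s=%d", names(table(x$slides$status)),
                              table(x$slides$status)), collapse = ", ")))
  }
  if (!is.null(x$patients)) {
    cat(sprintf("  patients: %d\n", nrow(x$patients)))
  }
  if (!is.null(x$stats)) {
    cat(sprintf("  statistics: %s\n",
                paste(setdiff(names(x$stats), "outcomes"), collapse = ", ")))
  }
  invisible(x)
}
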