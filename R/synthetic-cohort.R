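#' Specify a simulated patient cohort
#'
#' Parameters for the cohort simulator. Biochemical-recurrence times follow
#' an exponential law with proportional-hazards covariate effects on the log
#' scale, the simplest law consistent with the Cox models used downstream
#' and the one that makes parameter-recovery tests exact in expectation.
#' Marker effects are either additive on the log hazard
#' (`effectModel = "additive"`: PTEN-low and non-diploid each contribute
#' their log-HR) or attached to the three-level combined marker
#' (`effectModel = "combined"`: separate log-HRs for the one-adverse and
#' both-adverse groups versus both-favorable).
#'
#' @param nPatients number of patients (>= 2).
#' @param prevalencePtenLow,prevalenceNondiploid marker prevalences in
#'   `[0, 1]`.
#' @param logHrPtenLow,logHrNondiploid additive log hazard ratios.
#' @param logHrOneAdverse,logHrBothAdverse group log hazard ratios for
#'   `effectModel = "combined"`.
#' @param effectModel `"additive"` or `"combined"`.
#' @param baselineHazard baseline event rate (events/year, > 0).
#' @param followupYears administrative censoring horizon (years).
#' @param psaVisitIntervalYears spacing of PSA follow-up visits (years).
#' @param psaRecurrenceLevel PSA value recorded at the event visit
#'   (ng/mL, >= 0.4).
#' @param scoreNoiseSd standard deviation of the noise separating the
#'   manual / automatic score readings from the underlying true score.
#' @param seed integer seed.
#' @return A validated list of class `"CohortParams"`.
#' @export
cohortParams <- function(nPatients = 259L,
                         prevalencePtenLow = 0.25,
                         prevalenceNondiploid = 0.27,
                         logHrPtenLow = log(3.32),
                         logHrNondiploid = log(1.98),
                         logHrOneAdverse = log(1.94),
                         logHrBothAdverse = log(4.63),
                         effectModel = c("additive", "combined"),
                         baselineHazard = 0.02,
                         followupYears = 10,
                         psaVisitIntervalYears = 0.25,
                         psaRecurrenceLevel = 0.5,
                         scoreNoiseSd = 0.04,
                         seed = 1L) {
  effectModel <- match.arg(effectModel)
  if (nPatients < 2L) stop("a cohort requires at least 2 patients")
  if (baselineHazard <= 0) stop("baselineHazard must be positive")
  if (prevalencePtenLow < 0 || prevalencePtenLow > 1 ||
      prevalenceNondiploid < 0 || prevalenceNondiploid > 1) {
    stop("prevalences must lie in [0, 1]")
  }
  if (followupYears < 0) stop("followupYears must be non-negative")
  if (psaRecurrenceLevel < 0.4) {
    stop("psaRecurrenceLevel must be at least the 0.4 ng/mL BCR threshold")
  }
  structure(as.list(environment()), class = "CohortParams")
}

#' Simulate a patient cohort with marker-dependent recurrence hazards
#'
#' Draws per-patient markers (true PTEN score with noisy manual/automatic
#' readings, DNA ploidy category, CAPRA-S base score, clinical covariates),
#' simulates biochemical-recurrence times from the proportional-hazards law
#' of the [cohortParams()], and lays a PSA follow-up series on the visit
#' grid: values stay below the 0.4 ng/mL threshold until the event, and the
#' first visit at or after the true event time records
#' `psaRecurrenceLevel`. Censored patients never reach the threshold.
#' Seeded and reproducible: identical params give identical tables.
#'
#' @param params a [cohortParams()].
#' @return A list with `patients` (one row per patient: markers, covariates,
#'   exclusion flags all `FALSE`, plus the generating truth `time_true` and
#'   `event_true`) and `psa` (long table: patient, time, psa).
#' @export
#' @examples
#' coh <- generateCohort(cohortParams(nPatients = 50, seed = 2))
#' head(coh$patients)
generateCohort <- function(params) {
  stopifnot(inherits(params, "CohortParams"))
  p <- params
  withSeed(p$seed, {
    n <- as.integer(p$nPatients)
    ptenLow <- stats::runif(n) < p$prevalencePtenLow
    trueScore <- ifelse(ptenLow,
                        0.5 * stats::rbeta(n, 2, 2),
                        0.5 + 0.5 * stats::rbeta(n, 2, 2))
    clamp <- function(v) pmin(pmax(v, 0), 1)
    manualScore <- clamp(trueScore + stats::rnorm(n, 0, p$scoreNoiseSd))
    autoScore <- clamp(trueScore + stats::rnorm(n, 0, p$scoreNoiseSd))
    nondiploid <- stats::runif(n) < p$prevalenceNondiploid
    ploidy <- ifelse(nondiploid,
                     ifelse(stats::runif(n) < 0.5, "tetraploid", "aneuploid"),
                     "diploid")
    capraBase <- sample(0L:10L, n, replace = TRUE,
                        prob = stats::dpois(0:10, 3))
    age <- round(stats::rnorm(n, 62, 5))

    loghr <- if (p$effectModel == "additive") {
      p$logHrPtenLow * ptenLow + p$logHrNondiploid * nondiploid
    } else {
      nAdv <- ptenLow + nondiploid
      ifelse(nAdv == 2L, p$logHrBothAdverse,
             ifelse(nAdv == 1L, p$logHrOneAdverse, 0))
    }
    tTrue <- stats::rexp(n, rate = p$baselineHazard * exp(loghr))
    eventTrue <- tTrue <= p$followupYears

    # per-patient schedule offset: staggered clinic visits avoid the massive
    # event-time ties (and the resulting grouped-data attenuation of hazard
    # ratios) that a shared calendar grid would create
    offsets <- stats::runif(n, 0.5, 1.5) * p$psaVisitIntervalYears
    pid <- tv <- vals <- vector("list", n)
    for (i in seq_len(n)) {
      if (p$followupYears < offsets[i]) next
      visits <- seq(offsets[i], p$followupYears, by = p$psaVisitIntervalYears)
      evVisit <- if (eventTrue[i]) which(visits >= tTrue[i])[1] else NA_integer_
      if (!is.na(evVisit)) {
        tv[[i]] <- visits[seq_len(evVisit)]
        vals[[i]] <- c(stats::runif(evVisit - 1L, 0.01, 0.2),
                       p$psaRecurrenceLevel)
      } else {
        tv[[i]] <- visits
        vals[[i]] <- stats::runif(length(visits), 0.01, 0.2)
      }
      pid[[i]] <- rep.int(i, length(tv[[i]]))
    }
    psa <- data.frame(
      patient = as.integer(unlist(pid)),
      time = as.numeric(unlist(tv)),
      psa = as.numeric(unlist(vals))
    )

    patients <- data.frame(
      patient = seq_len(n),
      true_score = trueScore,
      manual_score = manualScore,
      auto_score = autoScore,
      pten_low_true = ptenLow,
      ploidy = ploidy,
      capra_s = capraBase,
      age = age,
      time_true = tTrue,
      event_true = eventTrue,
      missing_consent = FALSE,
      short_followup = FALSE,
      no_tumor_material = FALSE,
      preoperative_therapy = FALSE,
      postoperative_death = FALSE,
      lost_followup = FALSE,
      stringsAsFactors = FALSE
    )
    list(patients = patients, psa = psa, params = p)
  })
}
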