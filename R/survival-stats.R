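#' Derive the biochemical-recurrence endpoint from a PSA series
#'
#' Biochemical recurrence (BCR) is a single post-operative PSA of at least
#' `threshold` (0.4 ng/mL). The event time is the first measurement at or
#' above the threshold; patients who never reach it are censored at their
#' final PSA registration. Times are years since surgery.
#'
#' @param psaTime numeric vector of positive measurement times (years since
#'   surgery).
#' @param psaValue numeric vector of PSA values (ng/mL), same length.
#' @param threshold BCR threshold, default 0.4 ng/mL.
#' @return A list of class `"Outcome"`: `time`, `event` (logical),
#'   `threshold`.
#' @export
#' @examples
#' deriveBcr(c(1, 2, 3), c(0.1, 0.2, 0.45))
deriveBcr <- function(psaTime, psaValue, threshold = 0.4) {
  stopifnot(length(psaTime) == length(psaValue))
  if (length(psaTime) == 0L) {
    stop("no post-surgery PSA measurements; patient must be excluded ",
         "(missing follow-up)")
  }
  if (any(psaTime <= 0)) stop("PSA times must be positive (years post surgery)")
  ord <- order(psaTime)
  psaTime <- psaTime[ord]; psaValue <- psaValue[ord]
  hit <- which(psaValue >= threshold)
  if (length(hit)) {
    out <- list(time = psaTime[hit[1]], event = TRUE, threshold = threshold)
  } else {
    out <- list(time = psaTime[length(psaTime)], event = FALSE,
                threshold = threshold)
  }
  structure(out, class = "Outcome")
}

#' @rdname deriveBcr
#' @param psa long-format data.frame with columns `patient`, `time`, `psa`.
#' @return `deriveBcrCohort`: data.frame with one row per patient
#'   (`patient`, `time`, `event`).
#' @export
deriveBcrCohort <- function(psa, threshold = 0.4) {
  stopifnot(all(c("patient", "time", "psa") %in% names(psa)))
  ord <- order(psa$patient, psa$time)
  byPat <- split(seq_len(nrow(psa))[ord], psa$patient[ord])
  res <- lapply(byPat, function(ix) {
    hit <- which(psa$psa[ix] >= threshold)
    if (length(hit)) c(psa$time[ix[hit[1]]], 1) else c(psa$time[ix[length(ix)]], 0)
  })
  out <- data.frame(
    patient = type.convert(names(byPat), as.is = TRUE),
    time = vapply(res, `[`, numeric(1), 1),
    event = vapply(res, `[`, numeric(1), 2) == 1,
    row.names = NULL
  )
  out[order(match(out$patient, unique(psa$patient))), , drop = FALSE]
}

#' Kaplan-Meier curves with medians
#'
#' Product-limit survival estimates per group via [survival::survfit()].
#'
#' @param time,event outcome vectors (event logical or 0/1).
#' @param group optional grouping factor; a single pooled curve when omitted.
#' @return A list: `table` (group, time, n_risk, n_event, n_censor, surv),
#'   `median` (named vector of median survival times, `NA` when not
#'   reached), and the underlying `survfit` object.
#' @export
kmCurve <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event))
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.factor(group)
  if (any(table(group) == 0L)) stop("every group must contain subjects")
  df <- data.frame(time = time, event = as.integer(event), group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  smry <- summary(fit, censored = TRUE)
  strat <- if (is.null(smry$strata)) {
    rep(levels(group)[1], length(smry$time))
  } else {
    sub("^group=", "", as.character(smry$strata))
  }
  tab <- data.frame(
    group = strat, time = smry$time, n_risk = smry$n.risk,
    n_event = smry$n.event, n_censor = smry$n.censor, surv = smry$surv,
    stringsAsFactors = FALSE
  )
  med <- summary(fit)$table
  medians <- if (is.null(dim(med))) {
    stats::setNames(med[["median"]], levels(group)[1])
  } else {
    stats::setNames(med[, "median"], sub("^group=", "", rownames(med)))
  }
  list(table = tab, median = medians, fit = fit)
}

#' Mantel-Cox log-rank test
#'
#' @param time,event outcome vectors.
#' @param group factor with at least two groups.
#' @return A list: `chisq`, `df` (k - 1), `p`.
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("log-rank test requires at least two groups")
  df <- data.frame(time = time, event = as.integer(event), group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(group)
  list(chisq = unname(sd$chisq), df = k - 1L,
       p = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE))
}

#' Cox proportional hazards fit with Wald tests
#'
#' Partial-likelihood estimation via [survival::coxph()] with the Efron tie
#' approximation. Reports per-coefficient hazard ratios with Wald 95%
#' confidence intervals, and a Wald chi-square test per covariate term
#' (multi-df for categorical covariates, whose first level is the reference).
#' Non-convergence or coefficient divergence (complete separation) is
#' reported via the `converged` flag and a warning, never silently.
#'
#' @param time,event outcome vectors.
#' @param covariates data.frame of covariates (factors get treatment
#'   contrasts against their first level).
#' @param level confidence level for the hazard-ratio intervals.
#' @return A list of class `"CoxResult"`: `coefficients` (data.frame with
#'   term, hr, lower, upper, p), `wald` (data.frame term, chisq, df, p),
#'   `converged`, `n`, `nevent`, and the `coxph` fit.
#' @export
coxFit <- function(time, event, covariates, level = 0.95) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  df <- cbind(data.frame(.time = time, .event = as.integer(event)), covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  ))
  fit <- survival::coxph(form, data = df, ties = "efron")
  if (sum(df$.event) < length(stats::coef(fit))) {
    stop("fewer events than model coefficients")
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  converged <- all(is.finite(beta)) && all(is.finite(se)) && all(abs(beta) < 15)
  if (!converged) {
    warning("Cox fit did not converge (possible complete separation); ",
            "estimates are unreliable")
  }
  coefs <- data.frame(
    term = names(beta),
    hr = exp(beta),
    lower = exp(beta - z * se),
    upper = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # multi-df Wald test per covariate term
  asg <- fit$assign
  V <- stats::vcov(fit)
  wald <- do.call(rbind, lapply(names(asg), function(term) {
    ix <- asg[[term]]
    b <- beta[ix]
    stat <- as.numeric(t(b) %*% solve(V[ix, ix, drop = FALSE]) %*% b)
    data.frame(term = term, chisq = stat, df = length(ix),
               p = stats::pchisq(stat, length(ix), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  structure(list(coefficients = coefs, wald = wald, converged = converged,
                 n = nrow(df), nevent = sum(df$.event), fit = fit),
            class = "CoxResult")
}

#' @export
print.CoxResult <- function(x, ...) {
  cat(sprintf("Cox fit: n = %d, events = %d%s\n", x$n, x$nevent,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}
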