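#' Harrell's concordance index with BCa bootstrap interval
#'
#' The probability that, of a comparable patient pair, the patient with the
#' higher risk score experiences the event first; tied scores count 0.5.
#' Computed with [survival::concordance()] (`reverse = TRUE`, so larger
#' scores mean higher risk). With `B > 0` a bias-corrected and accelerated
#' (BCa) percentile bootstrap interval is attached, resampling patients.
#'
#' @param time,event outcome vectors.
#' @param risk numeric risk scores (larger = higher risk).
#' @param B number of bootstrap replicates for the CI (0 to skip; the
#'   reference analysis uses 10,000).
#' @param level confidence level.
#' @param seed integer seed for the bootstrap.
#' @return A list of class `"ConcordanceResult"`: `cindex`, `lower`, `upper`,
#'   `level`, `B`, `seed`, and the pair counts.
#' @export
harrellCindex <- function(time, event, risk, B = 0L, level = 0.95, seed = 1L) {
  stopifnot(length(time) == length(event), length(risk) == length(time))
  if (length(time) < 2L) stop("no comparable pairs; c-index is undefined")
  cc <- cstat(time, event, risk)
  if (is.na(cc$cindex)) stop("no comparable pairs; c-index is undefined")
  if (cc$comparable < 2) stop("at least two comparable pairs are required")
  out <- list(cindex = cc$cindex, lower = NA_real_, upper = NA_real_,
              level = level, B = as.integer(B), seed = as.integer(seed),
              concordant = cc$concordant, discordant = cc$discordant,
              tied = cc$tied)
  if (B > 0) {
    df <- data.frame(time = time, event = as.integer(event), risk = risk)
    ci <- bcaCi(df, function(d, i) cstat(d$time[i], d$event[i], d$risk[i])$cindex,
                B = B, level = level, seed = seed)
    out$lower <- ci$lower
    out$upper <- ci$upper
  }
  structure(out, class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Harrell's c-index: %.4f", x$cindex))
  if (x$B > 0) {
    cat(sprintf(" (%d%% BCa CI %.4f to %.4f, B = %d)",
                round(100 * x$level), x$lower, x$upper, x$B))
  }
  cat("\n")
  invisible(x)
}

# Harrell's c for right-censored data; ties in score count 0.5.
cstat <- function(time, event, risk) {
  cc <- survival::concordance(
    survival::Surv(time, as.integer(event)) ~ risk, reverse = TRUE)
  cnt <- cc$count
  comparable <- cnt[["concordant"]] + cnt[["discordant"]] + cnt[["tied.x"]]
  list(cindex = if (comparable > 0) unname(cc$concordance) else NA_real_,
       concordant = unname(cnt[["concordant"]]),
       discordant = unname(cnt[["discordant"]]),
       tied = unname(cnt[["tied.x"]]),
       comparable = unname(comparable))
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' Nonparametric BCa percentile interval: the bias correction z0 comes from
#' the proportion of bootstrap replicates below the point estimate, the
#' acceleration from the jackknife skewness, and the interval endpoints are
#' quantiles of the bootstrap distribution at the adjusted probabilities.
#' Resampling is by row (the patient is the resampling unit); `strata`
#' resamples within strata. Replicates where the statistic is undefined
#' (`NA`) are dropped and counted.
#'
#' @param data vector or data.frame of observations.
#' @param statistic function(data, indices) returning a scalar.
#' @param B number of bootstrap replicates (at least 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @param strata optional stratification vector (length `NROW(data)`).
#' @return A list of class `"BcaInterval"`: `estimate`, `lower`, `upper`,
#'   `level`, `B`, `seed`, `z0`, `accel`, `degenerate` (TRUE when all
#'   replicates are equal and the interval collapses to a point), `nDropped`.
#' @export
#' @examples
#' bcaCi(rnorm(30), function(d, i) mean(d[i]), B = 200, seed = 1)$estimate
bcaCi <- function(data, statistic, B = 10000L, level = 0.95, seed = 1L,
                  strata = NULL) {
  n <- NROW(data)
  stopifnot(B >= 100L, n >= 2L)
  idxAll <- seq_len(n)
  theta <- statistic(data, idxAll)
  if (!is.finite(theta)) stop("statistic is undefined on the full sample")
  reps <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- if (is.null(strata)) {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(lapply(split(idxAll, strata), function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
      }
      statistic(data, idx)
    }, numeric(1))
  })
  nDropped <- sum(!is.finite(reps))
  reps <- reps[is.finite(reps)]
  jack <- vapply(idxAll, function(i) statistic(data, idxAll[-i]), numeric(1))
  accel <- jackknifeAcceleration(jack)
  res <- bcaFromReplicates(theta, reps, accel, level)
  structure(c(list(estimate = theta), res,
              list(level = level, B = as.integer(B), seed = as.integer(seed),
                   accel = accel, nDropped = nDropped)),
            class = "BcaInterval")
}

jackknifeAcceleration <- function(jack) {
  jack <- jack[is.finite(jack)]
  d <- mean(jack) - jack
  denom <- sum(d^2)^1.5
  if (denom < 1e-30) 0 else sum(d^3) / (6 * denom)
}

# Interval from a fixed replicate set (reused across confidence levels by
# the c-index difference test).
bcaFromReplicates <- function(theta, reps, accel, level) {
  if (length(reps) < 2L || stats::sd(reps) == 0) {
    return(list(lower = theta, upper = theta, z0 = 0, degenerate = TRUE))
  }
  propBelow <- (sum(reps < theta) + 0.5 * sum(reps == theta)) / length(reps)
  propBelow <- min(max(propBelow, 1 / (2 * length(reps))),
                   1 - 1 / (2 * length(reps)))
  z0 <- stats::qnorm(propBelow)
  alpha <- (1 - level) / 2
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - accel * (z0 + zq)))
  qs <- stats::quantile(reps, probs = adj, names = FALSE, type = 6)
  list(lower = qs[1], upper = qs[2], z0 = z0, degenerate = FALSE)
}

#' @export
print.BcaInterval <- function(x, ...) {
  cat(sprintf("%.5f (%d%% BCa CI %.5f to %.5f, B = %d%s)\n",
              x$estimate, round(100 * x$level), x$lower, x$upper, x$B,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Concordance-difference test between two risk scores
#'
#' Paired patient bootstrap of the difference in Harrell's c-index between
#' two risk scores on the same subjects. The two-sided p-value is one minus
#' the confidence level of the largest BCa interval that does not contain
#' zero, located by bisection on the confidence level (to `tol`); by
#' construction p < 0.05 exactly when the 95% BCa interval excludes zero.
#'
#' @param time,event outcome vectors.
#' @param scoreA,scoreB risk score vectors on the same subjects.
#' @param B bootstrap replicates (default 10,000).
#' @param level confidence level for the reported interval.
#' @param seed integer seed.
#' @param tol bisection precision on the confidence level.
#' @return A list of class `"CindexDifference"`: `delta` (cA - cB), `cA`,
#'   `cB`, `lower`, `upper` (BCa interval at `level`), `p`, `B`, `seed`.
#' @export
cindexDifferenceTest <- function(time, event, scoreA, scoreB, B = 10000L,
                                 level = 0.95, seed = 1L, tol = 1e-4) {
  stopifnot(length(scoreA) == length(time), length(scoreB) == length(time))
  df <- data.frame(time = time, event = as.integer(event),
                   a = scoreA, b = scoreB)
  stat <- function(d, i) {
    cstat(d$time[i], d$event[i], d$a[i])$cindex -
      cstat(d$time[i], d$event[i], d$b[i])$cindex
  }
  n <- nrow(df)
  theta <- stat(df, seq_len(n))
  reps <- withSeed(seed, {
    vapply(seq_len(B), function(bb) {
      stat(df, sample.int(n, n, replace = TRUE))
    }, numeric(1))
  })
  reps <- reps[is.finite(reps)]
  jack <- vapply(seq_len(n), function(i) stat(df, seq_len(n)[-i]), numeric(1))
  accel <- jackknifeAcceleration(jack)
  ci <- bcaFromReplicates(theta, reps, accel, level)
  excludes <- function(lev) {
    r <- bcaFromReplicates(theta, reps, accel, lev)
    r$lower > 0 || r$upper < 0
  }
  lo <- tol; hi <- 1 - tol
  p <- if (ci$degenerate || !excludes(lo)) {
    1
  } else if (excludes(hi)) {
    tol
  } else {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (excludes(mid)) lo <- mid else hi <- mid
    }
    1 - lo
  }
  structure(list(delta = theta,
                 cA = cstat(df$time, df$event, df$a)$cindex,
                 cB = cstat(df$time, df$event, df$b)$cindex,
                 lower = ci$lower, upper = ci$upper, level = level,
                 p = p, B = as.integer(B), seed = as.integer(seed)),
            class = "CindexDifference")
}

#' @export
print.CindexDifference <- function(x, ...) {
  cat(sprintf(
    "c-index difference: %.4f (%d%% BCa CI %.4f to %.4f), p = %.4g\n",
    x$delta, round(100 * x$level), x$lower, x$upper, x$p))
  invisible(x)
}

#' ROC area under the curve with BCa interval
#'
#' AUC of a continuous score against a binary truth, equal to the normalized
#' Mann-Whitney two-sample rank statistic. Computed with [pROC::roc()];
#' the optional BCa interval bootstraps subjects stratified by class.
#'
#' @param truth binary vector (logical, 0/1, or two-level factor).
#' @param score numeric scores (larger = more likely positive).
#' @param B bootstrap replicates for the CI (0 to skip).
#' @param level confidence level.
#' @param seed integer seed.
#' @return A list: `auc`, `lower`, `upper`, `level`, `B`.
#' @export
rocAuc <- function(truth, score, B = 0L, level = 0.95, seed = 1L) {
  y <- as.integer(as.factor(truth)) - 1L
  if (length(unique(y[!is.na(y)])) != 2L) {
    stop("both classes must be present to compute an AUC")
  }
  aucOf <- function(yy, ss) {
    as.numeric(pROC::auc(pROC::roc(yy, ss, quiet = TRUE, direction = "<",
                                   levels = c(0, 1))))
  }
  est <- aucOf(y, score)
  out <- list(auc = est, lower = NA_real_, upper = NA_real_, level = level,
              B = as.integer(B))
  if (B > 0) {
    df <- data.frame(y = y, s = score)
    ci <- bcaCi(df, function(d, i) {
      if (length(unique(d$y[i])) < 2L) return(NA_real_)
      aucOf(d$y[i], d$s[i])
    }, B = B, level = level, seed = seed, strata = y)
    out$lower <- ci$lower
    out$upper <- ci$upper
  }
  out
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @param level confidence level.
#' @return A list: `r`, `lower`, `upper`, `p`, `n`.
#' @export
pearsonR <- function(x, y, level = 0.95) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("Pearson correlation requires n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation is undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = level)
  list(r = unname(ct$estimate), lower = ct$conf.int[1],
       upper = ct$conf.int[2], p = ct$p.value, n = length(x))
}
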