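test_that("BCR is the first PSA at or above 0.4 ng/mL", {
  o <- deriveBcr(c(1, 2, 3), c(0.1, 0.2, 0.45))
  expect_true(o$event)
  expect_equal(o$time, 3)
  # exactly 0.4 is an event
  o <- deriveBcr(c(0.5, 1.5), c(0.39, 0.4))
  expect_true(o$event)
  expect_equal(o$time, 1.5)
  # later dips do not cancel the first crossing
  o <- deriveBcr(c(1, 2, 3), c(0.6, 0.1, 0.1))
  expect_true(o$event)
  expect_equal(o$time, 1)
  # never reaching: censored at the last registration
  o <- deriveBcr(c(1, 2, 3), c(0.1, 0.2, 0.3))
  expect_false(o$event)
  expect_equal(o$time, 3)
  # unordered input is sorted by time first
  o <- deriveBcr(c(3, 1, 2), c(0.45, 0.1, 0.2))
  expect_true(o$event)
  expect_equal(o$time, 3)
  expect_error(deriveBcr(numeric(), numeric()), "no post-surgery PSA")
  expect_error(deriveBcr(c(0, 1), c(0.1, 0.1)), "positive")
})

test_that("cohort BCR derivation agrees with the per-patient function", {
  coh <- generateCohort(cohortParams(nPatients = 30, seed = 8))
  out <- deriveBcrCohort(coh$psa)
  for (p in out$patient) {
    sub <- coh$psa[coh$psa$patient == p, ]
    o <- deriveBcr(sub$time, sub$psa)
    expect_equal(out$time[out$patient == p], o$time)
    expect_equal(out$event[out$patient == p], o$event)
  }
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  # 6 subjects: events at 1, 2, 4, 6; censored at 3 and 5
  time <- 1:6
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  km <- kmCurve(time, event)
  tab <- km$table
  sAt <- function(t) tab$surv[tab$time == t]
  expect_equal(sAt(1), 5 / 6)
  expect_equal(sAt(2), 5 / 6 * 4 / 5)
  expect_equal(sAt(4), 5 / 6 * 4 / 5 * 2 / 3)
  expect_equal(sAt(6), 0)
  # without censoring KM is the empirical survival function
  set.seed(5)
  t2 <- sort(sample(1:100, 20))
  km2 <- kmCurve(t2, rep(TRUE, 20))
  for (tt in km2$table$time) {
    expect_equal(km2$table$surv[km2$table$time == tt], mean(t2 > tt))
  }
})

test_that("log-rank test matches an observed-minus-expected oracle", {
  d <- fxSurvData(60, seed = 21)
  grp <- d$risk > 0
  lr <- logrankTest(d$time, d$event, grp)
  expect_equal(lr$chisq, bruteLogrank(d$time, d$event, grp), tolerance = 1e-10)
  expect_equal(lr$p, pchisq(lr$chisq, 1, lower.tail = FALSE))
  expect_identical(lr$df, 1L)
  # two copies of the same group: no difference by construction
  lr0 <- logrankTest(rep(d$time, 2), rep(d$event, 2),
                     rep(c("a", "b"), each = 60))
  expect_lt(lr0$chisq, 1e-10)
  expect_error(logrankTest(d$time, d$event, rep("a", 60)), "two groups")
})

test_that("Cox fit reports per-coefficient and per-term Wald results", {
  d <- fxSurvData(120, seed = 22)
  cf <- coxFit(d$time, d$event, data.frame(risk = d$risk))
  expect_true(cf$converged)
  co <- cf$coefficients
  # generating model used log HR 0.8 per unit risk
  expect_gt(co$hr, 1)
  expect_true(co$lower <= exp(0.8))
  # single-df Wald test equals the squared coefficient z-test
  expect_equal(cf$wald$chisq, qchisq(co$p, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(cf$wald$p, co$p, tolerance = 1e-12)
  # a three-level factor yields one 2-df term
  g <- factor(sample(c("x", "y", "z"), 120, replace = TRUE))
  cf2 <- coxFit(d$time, d$event, data.frame(risk = d$risk, g = g))
  expect_identical(cf2$wald$df, c(1L, 2L))
  expect_identical(nrow(cf2$coefficients), 3L)
  # more coefficients than events is an error
  suppressWarnings(expect_error(
    coxFit(d$time[1:8], rep(c(TRUE, FALSE), c(1, 7)),
           data.frame(a = rnorm(8), b = rnorm(8))),
    "fewer events"))
})

test_that("Harrell's c-index equals exhaustive pair counting", {
  d <- fxSurvData(50, seed = 23)
  # inject score ties to exercise the 0.5 rule
  risk <- round(d$risk, 1)
  got <- harrellCindex(d$time, d$event, risk)$cindex
  expect_equal(got, bruteCindex(d$time, d$event, risk), tolerance = 1e-12)
  # constant score: every comparable pair is tied
  expect_equal(harrellCindex(d$time, d$event, rep(1, 50))$cindex, 0.5)
  # perfect and anti-perfect orderings without censoring
  t0 <- 1:20
  expect_equal(harrellCindex(t0, rep(TRUE, 20), -t0)$cindex, 1)
  expect_equal(harrellCindex(t0, rep(TRUE, 20), t0)$cindex, 0)
  expect_error(harrellCindex(1, TRUE, 0.3), "length|comparable")
})

test_that("ROC AUC is the normalized Mann-Whitney statistic", {
  set.seed(24)
  y <- rep(c(0, 1), c(30, 20))
  s <- rnorm(50) + y
  a <- rocAuc(y, s)$auc
  w <- wilcox.test(s[y == 1], s[y == 0], exact = FALSE)$statistic
  expect_equal(a, unname(w) / (30 * 20), tolerance = 1e-12)
  expect_equal(rocAuc(y, y)$auc, 1)
  expect_equal(rocAuc(y, rep(0, 50))$auc, 0.5)
  expect_error(rocAuc(rep(1, 10), rnorm(10)), "both classes")
})

test_that("AUC of a binary-time outcome equals the c-index identity", {
  # with all subjects experiencing the event and only two event times, the
  # c-index of a score reduces to the AUC for predicting the earlier time
  set.seed(25)
  y <- rep(c(0, 1), each = 25)
  s <- rnorm(50) + 0.8 * y
  time <- ifelse(y == 1, 1, 2) # higher score -> earlier event
  ci <- harrellCindex(time, rep(TRUE, 50), s)$cindex
  expect_equal(ci, rocAuc(y, s)$auc, tolerance = 1e-12)
})

test_that("Pearson correlation matches the covariance formula", {
  set.seed(26)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  r <- pearsonR(x, y)
  expect_equal(r$r, cov(x, y) / (sd(x) * sd(y)), tolerance = 1e-12)
  expect_identical(r$n, 40L)
  expect_lt(r$lower, r$r)
  expect_gt(r$upper, r$r)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonR(1:2, 1:2), "n >= 3")
})
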