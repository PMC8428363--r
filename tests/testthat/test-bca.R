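test_that("BCa interval agrees with the boot package on a skewed statistic", {
  set.seed(31)
  x <- rexp(40)
  ours <- bcaCi(x, function(d, i) mean(d[i]), B = 4000, seed = 7)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  bci <- boot::boot.ci(bt, type = "bca")$bca
  # different RNG streams: endpoints agree to bootstrap noise
  expect_equal(ours$lower, bci[4], tolerance = 0.03)
  expect_equal(ours$upper, bci[5], tolerance = 0.03)
  expect_equal(ours$estimate, mean(x))
})

test_that("BCa reduces toward the percentile interval for a symmetric statistic", {
  set.seed(32)
  x <- rnorm(200)
  ours <- bcaCi(x, function(d, i) mean(d[i]), B = 4000, seed = 9)
  # symmetric sampling distribution: bias correction and acceleration small
  expect_lt(abs(ours$z0), 0.1)
  expect_lt(abs(ours$accel), 0.05)
  reps <- PTENpipe:::withSeed(9, {
    vapply(1:4000, function(b) mean(x[sample.int(200, 200, TRUE)]), numeric(1))
  })
  pct <- quantile(reps, c(0.025, 0.975), type = 6, names = FALSE)
  expect_lt(abs(ours$lower - pct[1]), 0.01)
  expect_lt(abs(ours$upper - pct[2]), 0.01)
  expect_false(ours$degenerate)
  expect_true(ours$lower < ours$estimate && ours$estimate < ours$upper)
})

test_that("a constant statistic collapses to a flagged point interval", {
  r <- bcaCi(rep(3, 20), function(d, i) mean(d[i]), B = 200, seed = 1)
  expect_true(r$degenerate)
  expect_equal(r$lower, 3)
  expect_equal(r$upper, 3)
})

test_that("stratified resampling preserves the per-stratum counts", {
  d <- data.frame(y = rep(c(0, 1), c(30, 10)))
  r <- bcaCi(d, function(dd, i) sum(dd$y[i]), B = 200, seed = 2,
             strata = d$y)
  # every stratified replicate holds exactly 10 positives
  expect_true(r$degenerate)
  expect_equal(r$estimate, 10)
})

test_that("nominal 95% BCa coverage for the mean is near 0.95", {
  hits <- vapply(1:120, function(s) {
    set.seed(1000 + s)
    x <- rexp(30)
    ci <- bcaCi(x, function(d, i) mean(d[i]), B = 400, seed = s)
    ci$lower <= 1 && 1 <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("identical scores give a null c-index difference with p = 1", {
  d <- fxSurvData(60, seed = 33)
  r <- cindexDifferenceTest(d$time, d$event, d$risk, d$risk,
                            B = 500, seed = 1)
  expect_equal(r$delta, 0)
  expect_equal(r$p, 1)
})

test_that("an informative score beats noise with a small p-value", {
  d <- fxSurvData(300, seed = 34)
  set.seed(35)
  noise <- rnorm(300)
  r <- cindexDifferenceTest(d$time, d$event, d$risk, noise,
                            B = 2000, seed = 2)
  expect_gt(r$delta, 0)
  expect_lt(r$p, 0.05)
  # p < 0.05 exactly when the 95% interval excludes zero
  expect_true(r$lower > 0 || r$upper < 0)
  # and the null comparison is consistent the other way
  d2 <- fxSurvData(60, seed = 36)
  set.seed(37)
  r2 <- cindexDifferenceTest(d2$time, d2$event, rnorm(60), rnorm(60),
                             B = 1000, seed = 3)
  expect_identical(r2$p >= 0.05, r2$lower <= 0 && r2$upper >= 0)
})

test_that("the bootstrap does not disturb the caller's RNG stream", {
  set.seed(38)
  x <- rnorm(20)
  before <- .Random.seed
  bcaCi(x, function(d, i) mean(d[i]), B = 200, seed = 4)
  expect_identical(.Random.seed, before)
})
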