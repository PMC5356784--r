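# Poisson partition estimator and its confidence interval.

test_that("lambda estimate matches the partition model on known counts", {
  expect_identical(estimateLambda(15000, 0), 0)
  expect_lt(abs(estimateLambda(15000, 74) - 0.004945542), 1e-8)
  # strictly increasing in the positive count at fixed total
  lam <- estimateLambda(rep(15000, 100), seq(10, 1000, length.out = 100))
  expect_true(all(diff(lam) > 0))
  expect_error(estimateLambda(10000, 10000), "saturated")
  expect_error(estimateLambda(0, 0), "nTotal")
  expect_error(estimateLambda(100, 120), "nPositive")
})

test_that("lambda estimate maximizes the binomial likelihood", {
  set.seed(11)
  n <- sample(2000:40000, 40L)
  k <- vapply(n, function(ni) sample.int(ni - 1L, 1L), integer(1))
  lamHat <- estimateLambda(n, k)
  lamGrid <- mapply(gridMaxLambda, n, k)
  expect_lt(max(abs(lamHat - lamGrid)), 1e-8)
})

test_that("confidence interval brackets the estimate and scales as 1/sqrt(n)", {
  ci <- lambdaCI(15000, 74)
  expect_true(ci$low <= ci$lambda && ci$lambda <= ci$high)
  expect_gt(ci$low, 0)
  # log-scale symmetry of the delta interval
  expect_equal(log(ci$high) - log(ci$lambda),
               log(ci$lambda) - log(ci$low), tolerance = 1e-10)
  # quadrupling droplets at a fixed positive fraction halves the width
  ci4 <- lambdaCI(60000, 296)
  expect_equal((ci$high - ci$low) / (ci4$high - ci4$low), 2,
               tolerance = 0.02)
  # alpha -> 1 collapses the interval onto the point estimate
  ci1 <- lambdaCI(100, 50, alpha = 1)
  expect_equal(ci1$low, ci1$lambda)
  expect_equal(ci1$high, ci1$lambda)
})

test_that("delta-method interval agrees with a parametric bootstrap", {
  set.seed(21)
  for (k in c(74L, 731L)) {
    ci <- lambdaCI(15000, k)
    boot <- bootstrapLambdaCI(15000, k, B = 6000L)
    expect_equal(ci$low, boot[1L], tolerance = 0.06)
    expect_equal(ci$high, boot[2L], tolerance = 0.06)
  }
})

test_that("degenerate wells yield flagged one-sided bounds, not errors", {
  zero <- estimateConcentration(15000, 0)
  expect_identical(concentration(zero), 0)
  expect_identical(ciLow(zero), 0)
  # exact upper bound: P(no positives | lambda = high) = alpha
  expect_equal(ciHigh(zero), -log(0.05) / 15000 / 1e-3)
  expect_identical(zero@flags, "zero_positive")

  sat <- estimateConcentration(15000, 15000)
  expect_true(isSaturated(sat))
  expect_identical(concentration(sat), Inf)
  expect_identical(ciHigh(sat), Inf)
  expect_gt(ciLow(sat), 0)
  expect_identical(sat@flags, "saturated_well")
})

test_that("concentration is lambda scaled by droplet volume", {
  est <- estimateConcentration(15000, 74)
  expect_equal(concentration(est), lambdaHat(est) / 1e-3)
  half <- estimateConcentration(15000, 74,
                                spec = DropletSpec(dropletVolumeNl = 2))
  expect_equal(concentration(half), concentration(est) / 2)
  expect_equal(ciHigh(half), ciHigh(est) / 2)
})

test_that("merging wells pools counts and reproduces k-fold droplets", {
  w <- data.frame(sample_id = "S1", well_id = c("A1", "A2"),
                  channel = "FAM", n_total = c(15000, 15000),
                  n_positive = c(100, 110))
  m <- mergeWells(w)
  expect_identical(m$n_total, 30000)
  expect_identical(m$n_positive, 210)
  expect_identical(m$n_wells, 2L)
  # k identical wells == one well with k-fold droplets, exactly
  k4 <- w[rep(1L, 4L), ]
  k4$well_id <- paste0("A", 1:4)
  m4 <- mergeWells(k4)
  expect_equal(estimateLambda(m4$n_total, m4$n_positive),
               estimateLambda(60000, 400))
  # identity on a single well
  one <- mergeWells(w[1L, ])
  expect_identical(one$n_total, w$n_total[1L])
  # invalid merges
  wBad <- w; wBad$channel <- c("FAM", "HEX")
  expect_error(mergeWells(wBad), "channels")
  wBad2 <- w; wBad2$sample_id <- c("S1", "S2")
  expect_error(mergeWells(wBad2), "samples")
})

test_that("quantifySamples emits one row per sample and channel", {
  set.seed(5)
  wells <- rbind(simulateSample("S1", 0, 60, nWells = 2,
                                dropletsPerWell = 15000),
                 simulateSample("S2", 1, 40, dropletsPerWell = 15000))
  q <- quantifySamples(wells)
  expect_identical(nrow(q), 4L)
  expect_setequal(q$channel, c("FAM", "HEX"))
  expect_identical(q$n_wells[q$sample_id == "S1"], c(2L, 2L))
  expect_true(all(q$ci_low <= q$conc_copies_per_ul &
                  q$conc_copies_per_ul <= q$ci_high))
})
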