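test_that("the two-group F statistic matches its closed form", {
  expect_equal(olsFStatistic(c(1, 2, 3, 4), c(0, 0, 1, 1)), 8)
  # cross-check against lm() on a larger random instance
  set.seed(1)
  y <- rnorm(20); x <- rep(c(0, 1), 10)
  expect_equal(olsFStatistic(y, x),
               unname(summary(lm(y ~ x))$fstatistic["value"]))

  f0 <- olsFStatistic(rep(2, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(as.numeric(f0), 0)
  expect_true(attr(f0, "degenerate"))

  expect_error(olsFStatistic(1:4, c(0, 0, 0, 0)), "both labels")
  expect_error(olsFStatistic(1:4, c(1, 1, 1, 1)), "both labels")
  expect_error(olsFStatistic(1:2, c(0, 1)), "length")
})

test_that("exhaustive enumeration is used on small designs", {
  p <- permutationFTest(c(1, 2, 3, 4), c(0, 0, 1, 1), seed = 1L)
  expect_true(p@exhaustive)
  expect_equal(sort(p@fNull), c(0, 0, 0.5, 0.5, 8, 8))
  expect_equal(p@pValue, 2 / 6)
  # strict comparison drops the ties at the observed value
  pStrict <- permutationFTest(c(1, 2, 3, 4), c(0, 0, 1, 1), seed = 1L,
                              comparison = "greater")
  expect_equal(pStrict@pValue, 0)
})

test_that("Monte-Carlo mode is seeded and converges to the exhaustive p", {
  set.seed(5)
  y <- rnorm(8); lab <- rep(c(0, 1), each = 4)
  pE <- permutationFTest(y, lab, nIterations = 1000L, seed = 1L)
  expect_true(pE@exhaustive)
  a <- permutationFTest(y, lab, nIterations = 500L, seed = 7L,
                        forceMonteCarlo = TRUE)
  b <- permutationFTest(y, lab, nIterations = 500L, seed = 7L,
                        forceMonteCarlo = TRUE)
  expect_false(a@exhaustive)
  expect_identical(a@pValue, b@pValue)

  big <- permutationFTest(y, lab, nIterations = 20000L, seed = 3L,
                          forceMonteCarlo = TRUE)
  expect_lt(abs(big@pValue - pE@pValue),
            3 * sqrt(pE@pValue * (1 - pE@pValue) / 20000) + 1e-4)
})

test_that("relabelling 0 and 1 leaves F and p unchanged", {
  set.seed(9)
  y <- rnorm(12); lab <- rep(c(0, 1), 6)
  a <- permutationFTest(y, lab, nIterations = 2000L, seed = 2L)
  b <- permutationFTest(y, 1 - lab, nIterations = 2000L, seed = 2L)
  expect_equal(a@fObserved, b@fObserved)
  expect_equal(a@pValue, b@pValue)
})

test_that("signed-slope variant is two-tailed and matches enumeration", {
  y <- c(1, 2, 3, 10); lab <- c(0, 0, 1, 1)
  p <- permutationFTest(y, lab, statistic = "slope", seed = 1L)
  expect_true(p@exhaustive)
  # direct oracle: all 6 arrangements of which two indices carry label 1
  slopes <- apply(combn(4, 2), 2,
                  function(ix) mean(y[ix]) - mean(y[-ix]))
  expect_equal(p@pValue, mean(abs(slopes) >= abs(mean(y[3:4]) -
                                                   mean(y[1:2])) - 1e-12))
})

test_that("label bootstrap variant returns a valid, seeded p", {
  set.seed(4)
  y <- rnorm(15); lab <- rep_len(c(0, 1), 15)
  a <- permutationFTest(y, lab, nIterations = 500L, seed = 11L,
                        bootstrapLabels = TRUE)
  b <- permutationFTest(y, lab, nIterations = 500L, seed = 11L,
                        bootstrapLabels = TRUE)
  expect_identical(a@pValue, b@pValue)
  expect_false(a@exhaustive)
  expect_gte(a@pValue, 0); expect_lte(a@pValue, 1)
})

test_that("a strong habitat-presence effect is detected at p <= 0.001", {
  set.seed(13)
  pct <- runif(100, 0, 100)
  base <- data.frame(county_id = 1:100, percent_suitable = pct)
  small <- vapply(1:30, function(i) {
    h <- generateHistoricalRecords(base, -5, 0.1, seed = 300L + i)
    k <- sum(h$presence)
    if (k < 3 || k > 97) return(NA)
    permutationFTest(h$percent_suitable, h$presence,
                     nIterations = 2000L, seed = i)@pValue <= 0.001
  }, NA)
  expect_gte(mean(small, na.rm = TRUE), 0.95)
})
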