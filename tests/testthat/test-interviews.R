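test_that("sighting reports normalize across all four formats", {
  expect_equal(normalizeSightingDate("calendar_year", 2005, 2015), 10L)
  expect_equal(normalizeSightingDate("years_ago", 7, 2015), 7L)
  expect_equal(normalizeSightingDate("decade", "1980s", 2015), 30L)
  expect_equal(normalizeSightingDate("decade", 1980, 2015), 30L)
  expect_equal(normalizeSightingDate("decade", "1980s", 2015,
                                     decadeRule = "start"), 35L)
  expect_equal(normalizeSightingDate("age_at_sighting", 20, 2015, 47), 27L)

  expect_error(normalizeSightingDate("calendar_year", 2020, 2015), "after")
  expect_error(normalizeSightingDate("age_at_sighting", 20, 2015), "age")
  expect_error(normalizeSightingDate("calendar_year", 2005, 1500),
               "plausible")
  expect_warning(out <- normalizeSightingDate("years_ago", "dunno", 2015),
                 "unparseable")
  expect_true(is.na(out))
})

test_that("vectorized normalization flags future sightings and counts them", {
  rec <- data.frame(
    reported_sighting = c(TRUE, TRUE, TRUE, FALSE),
    raw_format = c("calendar_year", "calendar_year", "years_ago", NA),
    raw_value = c("2010", "2020", "bad", NA),
    interview_year = c(2015, 2015, 2015, 2015),
    age = c(50, 50, 50, 50))
  out <- normalizeSightingDates(rec)
  expect_equal(out$years_before_interview, c(5L, NA, NA, NA))
  expect_identical(attr(out, "nFlagged"), 1L)
  expect_identical(attr(out, "nUnparseable"), 1L)
})

test_that("county summaries aggregate reports and recency correctly", {
  rec <- data.frame(
    county_id = rep(c(1L, 2L), each = 4),
    province = "P1", selection_method = 0L,
    reported_sighting = c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 4)),
    raw_format = c("years_ago", "years_ago", NA, NA, rep(NA, 4)),
    raw_value = c("3", "10", NA, NA, rep(NA, 4)),
    interview_year = 2015, age = 60)
  cs <- summarizeCounties(rec)
  expect_equal(cs$proportion_reported, c(0.5, 0))
  expect_equal(cs$min_years_ago, c(3, NA))
  expect_equal(cs$mean_years_ago, c(6.5, 0))  # zero-filled mean by default
  csNA <- summarizeCounties(rec, meanYearsZeroFill = FALSE)
  expect_equal(csNA$mean_years_ago, c(6.5, NA))
  expect_equal(nrow(summarizeCounties(rec[0, ])), 0L)

  recency <- summarizeCounties(data.frame(
    county_id = 1L, province = "P1", selection_method = 1L,
    reported_sighting = rep(TRUE, 3),
    raw_format = "years_ago", raw_value = c("3", "10", "25"),
    interview_year = 2015, age = 70))
  expect_equal(recency$min_years_ago, 3)
  expect_equal(recency$mean_years_ago, mean(c(3, 10, 25)))
})

test_that("the 2x2 chi-squared reproduces published and textbook values", {
  # counties yielding sighting reports: 43/48 historical vs 40/47 model
  res <- contingencyChi2(matrix(c(43, 40, 5, 7), 2))
  expect_equal(round(res$chi2, 2), 0.12)
  expect_equal(round(res$p, 2), 0.73)
  expect_identical(res$df, 1L)

  flat <- contingencyChi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)

  # Yates closed form N(|ad - bc| - N/2)^2 / (r1 r2 c1 c2)
  diag20 <- contingencyChi2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(round(diag20$chi2, 1), 36.1)

  # with correction off, the classical Pearson statistic
  set.seed(2)
  for (i in 1:10) {
    m <- matrix(rpois(4, 20) + 1, 2)
    res <- contingencyChi2(m, correction = FALSE)
    N <- sum(m)
    pearson <- N * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m), colSums(m))
    expect_equal(res$chi2, pearson)
  }

  expect_error(contingencyChi2(matrix(c(5, 5, 0, 0), 2)), "margins")
  expect_error(contingencyChi2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("dataset descriptives recompute the printed percentages", {
  tiny <- data.frame(county_id = 1L, reported_sighting = c(TRUE, TRUE,
                                                           FALSE, FALSE),
                     age = c(30, 40, 50, 60), sex = "male")
  expect_equal(datasetDescriptives(tiny)$pct_reported, 50.0)

  # survey-scale counts: 1,299 of 2,812 reporting, 1,146 dated
  n <- 2812L; nRep <- 1299L; nDated <- 1146L
  rec <- data.frame(
    county_id = rep_len(1:95, n),
    reported_sighting = rep(c(TRUE, FALSE), c(nRep, n - nRep)),
    years_before_interview = c(rep(5L, nDated), rep(NA, n - nDated)),
    age = 47, sex = rep_len(c("male", "female"), n))
  d <- datasetDescriptives(rec)
  expect_equal(d$pct_reported, 46.2)
  expect_equal(d$pct_dated, 40.8)
  expect_equal(d$n_respondents, 2812L)
})
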