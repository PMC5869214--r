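test_that("landscape generation is deterministic and respects its config", {
  cfg <- landscapeConfig(gridRows = 100L, gridCols = 100L, nCounties = 16L,
                         nProvinces = 4L, elevationRange = c(0, 3000),
                         seed = 11L)
  a <- generateLandscape(cfg)
  b <- generateLandscape(cfg)
  expect_identical(gridValues(a$elevation), gridValues(b$elevation))
  expect_identical(gridValues(a$landcover), gridValues(b$landcover))
  expect_identical(gridValues(a$countyLabels), gridValues(b$countyLabels))
  expect_identical(a$countyProvince, b$countyProvince)
  expect_identical(gridValues(a$monthlyTemperature[[3]]),
                   gridValues(b$monthlyTemperature[[3]]))

  ev <- gridValues(a$elevation)
  expect_true(all(ev >= 0 & ev <= 3000))

  # total partition into exactly 16 contiguous labels
  lab <- gridValues(a$countyLabels)
  counts <- table(lab)
  expect_identical(sort(as.numeric(names(counts))), as.numeric(1:16))
  expect_true(all(counts >= 1))
  expect_equal(sum(counts), 100 * 100)

  # county -> province is a total function onto <= nProvinces provinces
  expect_equal(a$countyProvince$county_id, 1:16)
  expect_true(all(!is.na(a$countyProvince$province)))
  expect_lte(length(unique(a$countyProvince$province)), 4L)

  expect_error(landscapeConfig(gridRows = 3L), "4 x 4")
  expect_error(landscapeConfig(nCounties = 4L, nProvinces = 6L),
               "nProvinces")
  expect_error(landscapeConfig(gridRows = 4L, gridCols = 4L,
                               nCounties = 20L), "degenerate")
})

test_that("historical records follow the logit link to percent suitable", {
  counties <- data.frame(county_id = 1:40, percent_suitable = 0)
  h <- generateHistoricalRecords(counties, intercept = 0,
                                 slopePerPercent = 0, seed = 1L)
  expect_true(all(attr(h, "groundTruth")$probability == 0.5))
  expect_error(generateHistoricalRecords(data.frame(county_id = 1), 0, 0),
               "percent_suitable")

  # null slope: permutation test rejects at about the nominal rate
  set.seed(42)
  pct <- runif(40, 0, 100)
  base <- data.frame(county_id = 1:40, percent_suitable = pct)
  rejections <- vapply(1:200, function(i) {
    h <- generateHistoricalRecords(base, 0, 0, seed = 1000L + i)
    if (sum(h$presence) == 0 || sum(h$presence) == 40) return(NA)
    permutationFTest(h$percent_suitable, h$presence, nIterations = 400L,
                     seed = i)@pValue <= 0.05
  }, NA)
  rate <- mean(rejections, na.rm = TRUE)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)

  # strong slope: presence counties carry more suitable habitat
  higher <- vapply(1:100, function(i) {
    h <- generateHistoricalRecords(base, -3, 0.1, seed = 2000L + i)
    if (sum(h$presence) == 0 || sum(h$presence) == 40) return(NA)
    mean(h$percent_suitable[h$presence == 1]) >
      mean(h$percent_suitable[h$presence == 0])
  }, NA)
  expect_gte(mean(higher, na.rm = TRUE), 0.95)
})

test_that("interview generator delivers the configured design and margins", {
  des <- referenceSurveyDesign()
  rec <- generateInterviews(des, surveyConfig(seed = 5L))
  expect_equal(nrow(rec), 95L * 30L)  # exactly 2,850 records

  # no random effects, no arm effect: pooled proportion near the baseline
  cfg0 <- surveyConfig(effectProbDiff = 0, provinceInterceptSD = 0,
                       countyOLRESD = 0, baselineReportProb = 0.45,
                       seed = 9L)
  rec0 <- generateInterviews(des, cfg0)
  se <- sqrt(0.45 * 0.55 / nrow(rec0))
  expect_lt(abs(mean(rec0$reported_sighting) - 0.45), 3 * se)

  # the marginal proportion converges at large per-county samples
  big <- generateInterviews(smallSurveyDesign(10L, 2L),
                            surveyConfig(respondentsPerCounty = 1000L,
                                         provinceInterceptSD = 0,
                                         countyOLRESD = 0, seed = 2L))
  expect_lt(abs(mean(big$reported_sighting) - 0.45), 0.02)

  expect_error(generateInterviews(des[0, ], surveyConfig()), "empty")
  expect_error(surveyConfig(baselineReportProb = 1.2), "strictly")
  expect_error(surveyConfig(provinceInterceptSD = -1), "SD")
  expect_error(surveyConfig(dateFormatMix = c(calendar_year = 1,
                                              years_ago = 0.5, decade = 0,
                                              age_at_sighting = 0)),
               "sum to 1")
})

test_that("every raw date format decodes back to the stored truth", {
  rec <- generateInterviews(referenceSurveyDesign(), surveyConfig(seed = 31L))
  rec <- normalizeSightingDates(rec)
  rep_i <- which(rec$reported_sighting)
  expect_gt(length(rep_i), 500)
  expect_true(all(c("calendar_year", "years_ago", "decade",
                    "age_at_sighting") %in% rec$raw_format[rep_i]))
  expect_equal(rec$years_before_interview[rep_i],
               rec$true_years_ago[rep_i])
  expect_identical(attr(rec, "nFlagged"), 0L)
})
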