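mkGrid <- function(v, ...) rasterGrid(matrix(v, 2, 2), origin = c(0, 2), ...)

test_that("climate aggregation: mean, sum and nodata propagation", {
  months <- lapply(1:12, function(m) mkGrid(14))
  expect_equal(gridValues(aggregateClimate(months, "mean"))[1, 1], 14)

  precip <- lapply(1:12, function(m) mkGrid(100))
  expect_equal(gridValues(aggregateClimate(precip, "sum"))[1, 1], 1200)

  withNA <- precip
  v <- gridValues(withNA[[5]]); v[1, 1] <- NA
  withNA[[5]] <- setGridValues(withNA[[5]], v)
  out <- aggregateClimate(withNA, "sum")
  expect_true(is.na(gridValues(out)[1, 1]))
  expect_equal(gridValues(out)[2, 2], 1200)

  expect_error(aggregateClimate(precip[1:11], "sum"), "12")
  bad <- precip
  bad[[2]] <- rasterGrid(matrix(100, 2, 2), origin = c(5, 2))
  expect_error(aggregateClimate(bad, "sum"), "aligned")
})

test_that("land-cover regrouping to a forest binary", {
  lc <- rasterGrid(matrix(c(2, 7, NA, 1), 2, 2), origin = c(0, 2))
  out <- gridValues(regroupLandcover(lc, c(1, 2, 3)))
  expect_equal(out[1, 1], 1)   # class 2 is forest
  expect_equal(out[2, 1], 0)   # class 7 (cropland analogue) is not
  expect_true(is.na(out[1, 2]))
  expect_equal(out[2, 2], 1)
  expect_error(regroupLandcover(lc, integer()), "non-empty")
})

test_that("layer alignment: identity, block upsampling, crs guard", {
  target <- rasterGrid(matrix(0, 4, 4), origin = c(0, 4), cellSize = 1)
  same <- rasterGrid(matrix(1:16, 4, 4), origin = c(0, 4), cellSize = 1)
  expect_identical(alignLayers(list(a = same), target)$a, same)

  coarse <- rasterGrid(matrix(c(1, 3, 2, 4), 2, 2), origin = c(0, 4),
                       cellSize = 2)
  up <- alignLayers(list(lc = coarse), target,
                    methods = c(lc = "nearest"))$lc
  v <- gridValues(up)
  expect_equal(v[1:2, 1:2], matrix(1, 2, 2))  # constant 2x2 blocks
  expect_equal(v[1:2, 3:4], matrix(2, 2, 2))
  expect_equal(v[3:4, 1:2], matrix(3, 2, 2))
  expect_equal(v[3:4, 3:4], matrix(4, 2, 2))

  other <- rasterGrid(matrix(0, 2, 2), origin = c(0, 4), cellSize = 2,
                      crsTag = "different")
  expect_error(alignLayers(list(x = other), target), "crs")
})

tbl1Layers <- function(elev, temp, precip, forest) {
  mk <- function(x) rasterGrid(matrix(x, 1, 1), origin = c(0, 1))
  list(elevation = mk(elev), temperature = mk(temp),
       precipitation = mk(precip), landcover = mk(forest))
}

test_that("the giant salamander envelope intersects all four conditions", {
  spec <- giantSalamanderEnvelope(1L)
  cell <- function(...) gridValues(applyEnvelope(tbl1Layers(...), spec))[1, 1]
  expect_equal(cell(500, 14.0, 1000, 1), 1)
  expect_equal(cell(2000, 14.0, 1000, 1), 0)   # too high
  expect_equal(cell(500, 14.0, 732.6, 1), 1)   # inclusive lower bound
  expect_equal(cell(190, 12.7, 732.6, 1), 1)   # all bounds inclusive
  expect_equal(cell(1330, 16.8, 5000, 1), 1)
  expect_equal(cell(500, 14.0, 700, 1), 0)     # too dry
  expect_equal(cell(500, 14.0, 1000, 0), 0)    # not forest
  expect_true(is.na(cell(NA, 14.0, 1000, 1)))  # nodata propagates

  expect_error(applyEnvelope(tbl1Layers(1, 1, 1, 1)[-2], spec),
               "temperature")
})

test_that("envelope output is binary, order-independent and idempotent", {
  set.seed(7)
  land <- generateLandscape(smallLandscapeConfig(seed = 3L))
  layers <- list(
    elevation = land$elevation,
    temperature = aggregateClimate(land$monthlyTemperature, "mean"),
    precipitation = aggregateClimate(land$monthlyPrecipitation, "sum"),
    landcover = regroupLandcover(land$landcover, 1L))
  spec <- giantSalamanderEnvelope(1L)
  suit <- applyEnvelope(layers, spec)
  expect_true(all(gridValues(suit) %in% c(0, 1, NA)))

  shuffled <- envelopeSpec(spec@conditions[c(3, 1, 4, 2)])
  expect_equal(gridValues(applyEnvelope(layers, shuffled)),
               gridValues(suit))

  # idempotence: the envelope of its own binary output is the output
  passThrough <- envelopeSpec(list(categoryCondition("suitability", 1)))
  again <- applyEnvelope(list(suitability = suit), passThrough)
  expect_equal(gridValues(again), gridValues(suit))
})
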