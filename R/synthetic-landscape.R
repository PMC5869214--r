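#' Landscape generator configuration
#'
#' Defines the synthetic study region: grid size, number of counties and
#' provinces, and the stochastic models for elevation, monthly climate and
#' land cover. Continuous fields are spatially autocorrelated (moving-average
#' smoothed white noise with a configurable correlation length), which
#' produces the contiguous suitable/unsuitable patches real climate surfaces
#' show. Monthly temperature combines a spatial field, a seasonal cosine
#' cycle and an elevation lapse; monthly precipitation combines a spatial
#' field with a wet-season cycle, floored at zero.
#'
#' @param gridRows,gridCols grid dimensions (>= 4 each)
#' @param cellSize cell side length, map units
#' @param nCounties number of counties (contiguous Voronoi zones)
#' @param nProvinces number of provinces (<= nCounties)
#' @param elevationRange (min, max) elevation in metres
#' @param temperatureParams (mean degC, spatial SD degC, seasonal amplitude
#'   degC)
#' @param precipitationParams (mean mm/month, spatial SD mm/month)
#' @param landcoverClasses data.frame with columns id, label, weight
#'   (positive relative areas)
#' @param autocorrelationLength smoothing kernel length in cells
#' @param elevationLapse temperature decrease per metre of elevation above
#'   the regional mean (degC/m)
#' @param seed integer seed; identical config + seed gives identical output
#' @return validated config list of class "LandscapeConfig"
#' @export
landscapeConfig <- function(gridRows = 100L, gridCols = 100L, cellSize = 1,
                            nCounties = 16L, nProvinces = 4L,
                            elevationRange = c(0, 3000),
                            temperatureParams = c(mean = 14, spatialSD = 1.5,
                                                  seasonalAmplitude = 8),
                            precipitationParams = c(mean = 80, spatialSD = 25),
                            landcoverClasses = data.frame(
                              id = 1:4,
                              label = c("forest", "shrub", "cropland", "urban"),
                              weight = c(0.45, 0.2, 0.25, 0.1)),
                            autocorrelationLength = 10L,
                            elevationLapse = 0.004,
                            seed = 1L) {
  cfg <- list(gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
              cellSize = cellSize, nCounties = as.integer(nCounties),
              nProvinces = as.integer(nProvinces),
              elevationRange = elevationRange,
              temperatureParams = temperatureParams,
              precipitationParams = precipitationParams,
              landcoverClasses = landcoverClasses,
              autocorrelationLength = as.integer(autocorrelationLength),
              elevationLapse = elevationLapse, seed = as.integer(seed))
  if (cfg$gridRows < 4L || cfg$gridCols < 4L)
    stop("grid must be at least 4 x 4")
  if (cfg$nProvinces > cfg$nCounties)
    stop("nProvinces must not exceed nCounties")
  if (cfg$nCounties > cfg$gridRows * cfg$gridCols)
    stop("fewer cells than counties: configuration is degenerate")
  if (any(cfg$landcoverClasses$weight <= 0))
    stop("land-cover class weights must be positive")
  if (diff(cfg$elevationRange) < 0)
    stop("elevationRange must be (min, max)")
  class(cfg) <- "LandscapeConfig"
  cfg
}

# spatially autocorrelated standard field: white noise smoothed by a
# separable circular box filter of the given length, then standardized
.smoothField <- function(nr, nc, len) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (len > 1L) {
    k <- rep(1 / len, len)
    z <- apply(z, 2L, function(col) stats::filter(col, k, circular = TRUE))
    z <- t(apply(z, 1L, function(row) stats::filter(row, k, circular = TRUE)))
  }
  (z - mean(z)) / sd(z)
}

.rescaleToRange <- function(f, lo, hi) {
  r <- range(f)
  if (r[1] == r[2]) return(matrix(lo, nrow(f), ncol(f)))
  lo + (f - r[1]) / (r[2] - r[1]) * (hi - lo)
}

#' Generate a synthetic landscape
#'
#' Produces the full raster stack the suitability analysis consumes:
#' elevation, 12 monthly mean temperatures, 12 monthly precipitation totals,
#' a categorical land-cover layer, a county-label raster (a total Voronoi
#' partition grown from random seed cells, so every county is contiguous),
#' and a county-to-province assignment obtained by clustering county seeds.
#' All layers share one georeference. Fully deterministic given the config
#' seed.
#'
#' @param config a \code{\link{landscapeConfig}}
#' @return list with elements \code{elevation}, \code{monthlyTemperature}
#'   (list of 12), \code{monthlyPrecipitation} (list of 12),
#'   \code{landcover}, \code{countyLabels} (all \linkS4class{RasterGrid}s)
#'   and \code{countyProvince} (data.frame county_id, province)
#' @export
generateLandscape <- function(config) {
  if (!inherits(config, "LandscapeConfig"))
    config <- do.call(landscapeConfig, config)
  set.seed(config$seed)
  nr <- config$gridRows; nc <- config$gridCols
  mk <- function(v) rasterGrid(v, origin = c(0, nr * config$cellSize),
                               cellSize = config$cellSize)

  fE <- .smoothField(nr, nc, config$autocorrelationLength)
  elev <- .rescaleToRange(fE, config$elevationRange[1], config$elevationRange[2])

  tp <- config$temperatureParams
  fT <- .smoothField(nr, nc, config$autocorrelationLength)
  tBase <- tp[[1]] + tp[[2]] * fT - config$elevationLapse * (elev - mean(elev))
  months <- 1:12
  seasonal <- cos(2 * pi * (months - 7) / 12)
  monthlyT <- lapply(months, function(m) mk(tBase + tp[[3]] * seasonal[m]))

  pp <- config$precipitationParams
  fP <- .smoothField(nr, nc, config$autocorrelationLength)
  monthlyP <- lapply(months, function(m)
    mk(pmax(pp[[1]] + pp[[2]] * fP + 0.4 * pp[[1]] * seasonal[m], 0)))

  lc <- config$landcoverClasses
  fL <- .smoothField(nr, nc, config$autocorrelationLength)
  breaks <- stats::quantile(fL, probs = cumsum(lc$weight / sum(lc$weight)))
  cls <- matrix(lc$id[1], nr, nc)
  for (i in seq_len(nrow(lc) - 1L))
    cls[fL > breaks[i]] <- lc$id[i + 1L]
  landcover <- mk(cls)

  # contiguous counties: nearest-seed (Voronoi) assignment in cell space
  seedIdx <- sample.int(nr * nc, config$nCounties)
  sr <- (seedIdx - 1L) %% nr + 1L
  sc <- (seedIdx - 1L) %/% nr + 1L
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  best <- rep(1L, nr * nc)
  bestD <- (rows - sr[1])^2 + (cols - sc[1])^2
  for (i in seq_len(config$nCounties)[-1]) {
    d <- (rows - sr[i])^2 + (cols - sc[i])^2
    take <- d < bestD            # strict: ties keep the lower county id
    best[take] <- i
    bestD[take] <- d[take]
  }
  countyLabels <- mk(matrix(as.numeric(best), nr, nc))

  if (config$nProvinces == config$nCounties) {
    cl <- seq_len(config$nCounties)
  } else {
    cl <- kmeans(cbind(sr, sc), centers = config$nProvinces,
                 nstart = 5)$cluster
  }
  countyProvince <- data.frame(county_id = seq_len(config$nCounties),
                               province = paste0("P", cl))

  list(elevation = mk(elev), monthlyTemperature = monthlyT,
       monthlyPrecipitation = monthlyP, landcover = landcover,
       countyLabels = countyLabels, countyProvince = countyProvince)
}

#' Simulate historical presence records from percent suitable habitat
#'
#' County-level presence is Bernoulli with
#' logit(P(presence)) = intercept + slopePerPercent * percent_suitable,
#' emulating gazetteer records whose probability rises with the share of
#' suitable habitat. The generating parameters and probabilities are
#' attached as the \code{groundTruth} attribute so tests never re-derive
#' truth from output.
#'
#' @param counties data.frame with a \code{percent_suitable} column in
#'   [0, 100]
#' @param intercept logit-scale intercept
#' @param slopePerPercent logit-scale slope per percentage point
#' @param seed integer seed
#' @return \code{counties} with a \code{presence} column (0/1) and a
#'   \code{groundTruth} attribute
#' @export
generateHistoricalRecords <- function(counties, intercept, slopePerPercent,
                                      seed = 1L) {
  if (is.null(counties$percent_suitable))
    stop("counties must carry a percent_suitable column")
  pct <- counties$percent_suitable
  if (any(is.na(pct)) || any(pct < 0 | pct > 100))
    stop("percent_suitable must lie in [0, 100] with no missing values")
  set.seed(seed)
  prob <- plogis(intercept + slopePerPercent * pct)
  counties$presence <- rbinom(length(prob), 1L, prob)
  attr(counties, "groundTruth") <- list(intercept = intercept,
                                        slopePerPercent = slopePerPercent,
                                        probability = prob, seed = seed)
  counties
}
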