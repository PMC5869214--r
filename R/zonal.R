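#' Rasterize zone polygons onto a target grid
#'
#' Assigns each target cell the id of the polygon containing its centre
#' (even-odd rule). Cells inside no polygon become nodata. Cell centres
#' lying exactly on a shared boundary go to the first-listed polygon; a cell
#' centre strictly interior to two polygons is an error (overlap is never
#' resolved silently).
#'
#' @param polygons named list: each element a two-column (x, y) vertex
#'   matrix; names are unique integer zone ids.
#' @param target \linkS4class{RasterGrid} supplying the output georeference.
#' @return integer-labelled RasterGrid
#' @export
rasterizeZones <- function(polygons, target) {
  ids <- names(polygons)
  if (is.null(ids) || anyDuplicated(ids))
    stop("polygons must be a named list with unique ids")
  ctr <- cellCentres(target)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  lab <- rep(NA_real_, length(px))
  interiorHits <- integer(length(px))
  for (i in seq_along(polygons)) {
    loc <- .pointInPolygon(px, py, polygons[[i]])
    interiorHits <- interiorHits + (loc == 2L)
    if (any(interiorHits > 1L))
      stop("overlapping polygons: a cell centre is interior to more than one zone")
    take <- loc > 0L & is.na(lab)  # boundary ties: first-listed wins
    lab[take] <- as.numeric(ids[i])
  }
  setGridValues(target, matrix(lab, nrow(target@values), ncol(target@values)))
}

# even-odd point-in-polygon; returns 0 = outside, 1 = on boundary, 2 = interior
.pointInPolygon <- function(px, py, poly, tol = 1e-12) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
    # boundary: point within tol of segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
      boundary <- boundary | d2 < tol
    } else {
      boundary <- boundary | ((px - x1)^2 + (py - y1)^2 < tol)
    }
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py - y1) * dx / dy
      inside <- xor(inside, crosses & (px < xint))
    }
  }
  out <- integer(length(px))
  out[inside] <- 2L
  out[boundary] <- 1L
  out
}

#' Percent suitable habitat per zone
#'
#' Zonal statistics of a binary suitability raster over an integer
#' zone-label raster: per zone, the number of assessed (non-nodata)
#' suitability cells, the number suitable, and the percentage. Nodata
#' suitability cells count in neither numerator nor denominator, so the
#' percentage reflects assessed area only; zones with no assessed cells get
#' \code{NA} percent.
#'
#' @param suitability binary \linkS4class{RasterGrid} (values 0/1/NA)
#' @param zones integer-labelled RasterGrid aligned with it
#' @return data.frame with columns zone_id, n_cells, n_suitable,
#'   percent_suitable
#' @export
percentSuitableByZone <- function(suitability, zones) {
  .stopifMisaligned(list(suitability, zones), "suitability and zone grids")
  s <- as.vector(gridValues(suitability))
  z <- as.vector(gridValues(zones))
  keep <- !is.na(z)
  s <- s[keep]; z <- z[keep]
  zid <- sort(unique(z))
  f <- factor(z, levels = zid)
  nCells <- as.integer(tapply(!is.na(s), f, sum))
  nSuit <- as.integer(tapply(ifelse(is.na(s), 0, s), f, sum))
  pct <- ifelse(nCells > 0, 100 * nSuit / nCells, NA_real_)
  data.frame(zone_id = as.integer(zid), n_cells = nCells,
             n_suitable = nSuit, percent_suitable = pct)
}
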