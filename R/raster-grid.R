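#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = northernmost row). \code{NA} marks
#'   nodata cells.
#' @param origin (x, y) of the upper-left corner.
#' @param cellSize cell side length (map units), > 0.
#' @param nodata sentinel value used when the grid is written to disk; must
#'   not collide with a valid cell value.
#' @param crsTag opaque coordinate-system tag. Operations that combine grids
#'   require identical tags; there is no on-the-fly reprojection.
#' @return a \linkS4class{RasterGrid}.
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4))
#' gridDim(g)
#' @export
rasterGrid <- function(values, origin = c(0, nrow(values)), cellSize = 1,
                       nodata = -9999, crsTag = "synthetic") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.na(values) & values == nodata))
    stop("a valid cell value collides with the nodata sentinel")
  new("RasterGrid", values = values, origin = as.numeric(origin),
      cellSize = as.numeric(cellSize), nodata = as.numeric(nodata),
      crsTag = crsTag)
}

#' @describeIn rasterGrid matrix of cell values (NA = nodata)
#' @param x a RasterGrid
#' @export
gridValues <- function(x) x@values

#' @describeIn rasterGrid (nrows, ncols)
#' @export
gridDim <- function(x) dim(x@values)

#' @describeIn rasterGrid cell side length
#' @export
cellSize <- function(x) x@cellSize

#' @describeIn rasterGrid coordinate-system tag
#' @export
crsTag <- function(x) x@crsTag

#' @describeIn rasterGrid (x, y) of the upper-left corner
#' @export
gridOrigin <- function(x) x@origin

#' Replace the value matrix of a grid, keeping its georeference
#' @param x a RasterGrid
#' @param values replacement matrix of identical dimensions
#' @return a RasterGrid
#' @export
setGridValues <- function(x, values) {
  if (!identical(dim(values), dim(x@values)))
    stop("replacement values must match the grid dimensions")
  out <- x
  out@values <- values
  storage.mode(out@values) <- "double"
  out
}

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[!is.na(object@values)]
  cat(sprintf("RasterGrid: %d x %d cells, cell size %g, crs '%s'\n",
              d[1], d[2], object@cellSize, object@crsTag))
  cat(sprintf("  origin (UL corner): (%g, %g)\n",
              object@origin[1], object@origin[2]))
  if (length(v))
    cat(sprintf("  values: [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(object@values))))
  else cat("  values: all nodata\n")
  invisible(object)
})

#' Cell-centre coordinates of a grid
#'
#' @param x a RasterGrid
#' @return list with matrices \code{x} and \code{y} of cell-centre
#'   coordinates, same shape as the grid (row 1 = north).
#' @export
cellCentres <- function(x) {
  d <- dim(x@values)
  cs <- x@cellSize
  xs <- x@origin[1] + (seq_len(d[2]) - 0.5) * cs
  ys <- x@origin[2] - (seq_len(d[1]) - 0.5) * cs
  list(x = matrix(rep(xs, each = d[1]), d[1], d[2]),
       y = matrix(rep(ys, times = d[2]), d[1], d[2]))
}

#' Test whether two grids share shape and georeference
#'
#' @param a,b RasterGrid objects
#' @param tol numeric tolerance for origin/cell-size comparison
#' @return logical
#' @export
sameGeoreference <- function(a, b, tol = 1e-9) {
  identical(dim(a@values), dim(b@values)) &&
    abs(a@cellSize - b@cellSize) < tol &&
    all(abs(a@origin - b@origin) < tol) &&
    identical(a@crsTag, b@crsTag)
}

.stopifMisaligned <- function(grids, what = "layers") {
  ref <- grids[[1]]
  for (g in grids[-1])
    if (!sameGeoreference(ref, g))
      stop(sprintf("%s are not aligned (shape, origin, cell size and crs must match)",
                   what))
  invisible(TRUE)
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (.asc): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of cell values, north first. The CRS tag is not representable in the
#' format and is supplied by the caller on read.
#'
#' @param x a RasterGrid
#' @param path file path
#' @param crsTag tag attached to the grid on read
#' @return \code{writeAsciiGrid} returns \code{path} invisibly;
#'   \code{readAsciiGrid} returns a \linkS4class{RasterGrid}.
#' @export
writeAsciiGrid <- function(x, path) {
  d <- dim(x@values)
  hdr <- c(
    sprintf("ncols %d", d[2]),
    sprintf("nrows %d", d[1]),
    sprintf("xllcorner %.10g", x@origin[1]),
    sprintf("yllcorner %.10g", x@origin[2] - d[1] * x@cellSize),
    sprintf("cellsize %.10g", x@cellSize),
    sprintf("NODATA_value %.10g", x@nodata)
  )
  v <- x@values
  v[is.na(v)] <- x@nodata
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE,
                                                digits = 15), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path, crsTag = "synthetic") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2])
  names(vals) <- tolower(kv[, 1])
  nr <- as.integer(vals["nrows"]); nc <- as.integer(vals["ncols"])
  body <- lines[-(1:6)]
  m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
              nrow = nr, ncol = nc, byrow = TRUE)
  m[m == vals["nodata_value"]] <- NA_real_
  rasterGrid(m,
             origin = c(vals["xllcorner"],
                        vals["yllcorner"] + nr * vals["cellsize"]),
             cellSize = vals["cellsize"], nodata = vals["nodata_value"],
             crsTag = crsTag)
}
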