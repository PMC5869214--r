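#' Build an envelope specification
#'
#' Helper constructors for the three condition kinds, and the default
#' Chinese giant salamander envelope: elevation 190--1,330 m a.s.l., mean
#' annual temperature 12.7--16.8 degrees C, annual precipitation >= 732.6 mm,
#' and membership of the forest land-cover classes. All comparisons are
#' inclusive: the published ranges are values attained at occupied sites, so
#' a cell exactly on a bound satisfies the condition.
#'
#' @param variable layer name the condition applies to
#' @param min,max inclusive bounds
#' @param classes integer ids forming the acceptable category set
#' @param conditions list of conditions built with the helpers
#' @return an \linkS4class{EnvelopeSpec} (or a condition list for the helpers)
#' @examples
#' spec <- envelopeSpec(list(
#'   intervalCondition("elevation", 190, 1330),
#'   intervalCondition("temperature", 12.7, 16.8),
#'   lowerBoundCondition("precipitation", 732.6),
#'   categoryCondition("landcover", 1L)
#' ))
#' @export
envelopeSpec <- function(conditions) new("EnvelopeSpec", conditions = conditions)

#' @rdname envelopeSpec
#' @export
intervalCondition <- function(variable, min, max)
  list(variable = variable, kind = "interval", min = min, max = max)

#' @rdname envelopeSpec
#' @export
lowerBoundCondition <- function(variable, min)
  list(variable = variable, kind = "lower_bound", min = min)

#' @rdname envelopeSpec
#' @export
categoryCondition <- function(variable, classes)
  list(variable = variable, kind = "category_set", classes = classes)

#' @rdname envelopeSpec
#' @param forestClasses ids regarded as forest in the land-cover layer
#' @export
giantSalamanderEnvelope <- function(forestClasses = 1L) {
  envelopeSpec(list(
    intervalCondition("elevation", 190, 1330),
    intervalCondition("temperature", 12.7, 16.8),
    lowerBoundCondition("precipitation", 732.6),
    categoryCondition("landcover", forestClasses)
  ))
}

setMethod("show", "EnvelopeSpec", function(object) {
  cat(sprintf("EnvelopeSpec with %d conditions:\n", length(object@conditions)))
  for (cond in object@conditions) {
    desc <- switch(cond$kind,
      interval = sprintf("%g <= x <= %g", cond$min, cond$max),
      lower_bound = sprintf("x >= %g", cond$min),
      category_set = sprintf("x in {%s}", paste(cond$classes, collapse = ", "))
    )
    cat(sprintf("  %-14s %s\n", cond$variable, desc))
  }
  invisible(object)
})

#' Aggregate 12 monthly climate layers to an annual layer
#'
#' Cellwise mean (temperature) or sum (precipitation totals) over the 12
#' months. Nodata in any month propagates to nodata in the output.
#'
#' @param monthly list of exactly 12 aligned \linkS4class{RasterGrid}s
#' @param mode "mean" or "sum"
#' @return a RasterGrid on the shared georeference
#' @export
aggregateClimate <- function(monthly, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (length(monthly) != 12L)
    stop("exactly 12 monthly layers are required, got ", length(monthly))
  .stopifMisaligned(monthly, "monthly layers")
  acc <- Reduce(`+`, lapply(monthly, gridValues))  # NA propagates
  if (mode == "mean") acc <- acc / 12
  setGridValues(monthly[[1]], acc)
}

#' Regroup a categorical land-cover layer into a forest/non-forest binary
#'
#' Cells in any of \code{forestClasses} become 1, all other valid cells 0,
#' nodata is preserved. Mirrors collapsing tree cover, shrub cover and
#' tree-cover/natural-vegetation mosaic into a single forest category.
#'
#' @param landcover categorical \linkS4class{RasterGrid}
#' @param forestClasses non-empty vector of class ids regarded as forest
#' @return binary RasterGrid
#' @export
regroupLandcover <- function(landcover, forestClasses) {
  if (length(forestClasses) == 0L)
    stop("forestClasses must be non-empty")
  v <- gridValues(landcover)
  out <- ifelse(is.na(v), NA_real_, as.numeric(v %in% forestClasses))
  out <- matrix(out, nrow(v), ncol(v))
  setGridValues(landcover, out)
}

#' Resample layers onto a common target grid
#'
#' Maps every target cell centre into each source layer and interpolates:
#' nearest-neighbour for categorical layers, bilinear for continuous ones.
#' Layers already on the target grid are returned unchanged. All layers must
#' share the target's CRS tag; there is no reprojection.
#'
#' @param layers named list of \linkS4class{RasterGrid}s
#' @param target RasterGrid defining the output georeference
#' @param methods named character vector, "nearest" or "bilinear" per layer;
#'   unnamed layers default to "bilinear"
#' @return named list of aligned RasterGrids
#' @export
alignLayers <- function(layers, target, methods = NULL) {
  out <- lapply(names(layers), function(nm) {
    meth <- if (!is.null(methods) && nm %in% names(methods))
      methods[[nm]] else "bilinear"
    .resampleGrid(layers[[nm]], target, meth)
  })
  names(out) <- names(layers)
  out
}

.resampleGrid <- function(src, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!identical(src@crsTag, target@crsTag))
    stop(sprintf("crs mismatch: '%s' vs '%s' (no on-the-fly reprojection)",
                 src@crsTag, target@crsTag))
  if (sameGeoreference(src, target)) return(src)
  ctr <- cellCentres(target)
  sv <- gridValues(src)
  d <- dim(sv)
  # fractional (row, col) position of each target centre in the source grid
  col <- (ctr$x - src@origin[1]) / src@cellSize + 0.5
  row <- (src@origin[2] - ctr$y) / src@cellSize + 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(row), 1), d[1])
    ci <- pmin(pmax(round(col), 1), d[2])
    vals <- sv[cbind(as.vector(ri), as.vector(ci))]
  } else {
    r0 <- pmin(pmax(floor(row), 1), d[1]); r1 <- pmin(r0 + 1, d[1])
    c0 <- pmin(pmax(floor(col), 1), d[2]); c1 <- pmin(c0 + 1, d[2])
    fr <- pmin(pmax(row - r0, 0), 1); fc <- pmin(pmax(col - c0, 0), 1)
    v00 <- sv[cbind(as.vector(r0), as.vector(c0))]
    v01 <- sv[cbind(as.vector(r0), as.vector(c1))]
    v10 <- sv[cbind(as.vector(r1), as.vector(c0))]
    v11 <- sv[cbind(as.vector(r1), as.vector(c1))]
    fr <- as.vector(fr); fc <- as.vector(fc)
    vals <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
      fr * ((1 - fc) * v10 + fc * v11)
  }
  out <- matrix(vals, nrow(target@values), ncol(target@values))
  setGridValues(target, out)
}

#' Apply a threshold envelope to aligned environmental layers
#'
#' A cell is suitable (1) iff every condition in the spec holds; unsuitable
#' (0) if any fails; nodata if any required input layer is nodata there
#' (absence of evidence is not evidence of unsuitability).
#'
#' @param layers named list of aligned \linkS4class{RasterGrid}s covering
#'   every variable named in the spec
#' @param spec an \linkS4class{EnvelopeSpec}
#' @return binary suitability RasterGrid
#' @export
applyEnvelope <- function(layers, spec) {
  validObject(spec)
  need <- vapply(spec@conditions, `[[`, "", "variable")
  missing <- setdiff(need, names(layers))
  if (length(missing))
    stop("envelope variable(s) missing from layers: ",
         paste(missing, collapse = ", "))
  .stopifMisaligned(layers[need], "envelope layers")
  ref <- layers[[need[1]]]
  ok <- matrix(TRUE, nrow(ref@values), ncol(ref@values))
  anyNA <- matrix(FALSE, nrow(ref@values), ncol(ref@values))
  for (cond in spec@conditions) {
    v <- gridValues(layers[[cond$variable]])
    anyNA <- anyNA | is.na(v)
    pass <- switch(cond$kind,
      interval = v >= cond$min & v <= cond$max,
      lower_bound = v >= cond$min,
      category_set = matrix(v %in% cond$classes, nrow(v), ncol(v))
    )
    pass[is.na(pass)] <- FALSE
    ok <- ok & pass
  }
  out <- ifelse(anyNA, NA_real_, as.numeric(ok))
  setGridValues(ref, matrix(out, nrow(ref@values), ncol(ref@values)))
}
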