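#' @import methods
#' @importFrom stats dbinom dnbinom dnorm dpois integrate kmeans optimize
#'   nlminb pchisq plogis qlogis rbinom rgamma rnbinom rnorm rpois runif
#'   sd var chisq.test rgeom filter setNames aggregate coef glm binomial
#' @importFrom utils head tail combn write.csv read.csv
NULL

#' Georeferenced raster grid
#'
#' A minimal single-band raster: a numeric matrix with an upper-left origin,
#' a square cell size, and an opaque CRS tag. Missing cells are stored as
#' \code{NA} internally; the \code{nodata} slot records the sentinel used on
#' disk. Row 1 is the northernmost row and cells are registered by their
#' centres with half-open pixel footprints.
#'
#' @slot values numeric matrix of cell values (\code{NA} = nodata).
#' @slot origin numeric length-2, (x, y) of the upper-left \emph{corner}.
#' @slot cellSize positive scalar, cell side length in map units.
#' @slot nodata scalar sentinel written to/read from disk for missing cells.
#' @slot crsTag opaque coordinate-system identifier; layers must share it.
#' @export
setClass("RasterGrid",
  representation(
    values = "matrix",
    origin = "numeric",
    cellSize = "numeric",
    nodata = "numeric",
    crsTag = "character"
  ),
  prototype(
    origin = c(0, 0), cellSize = 1, nodata = -9999, crsTag = "synthetic"
  )
)

setValidity("RasterGrid", function(object) {
  msgs <- character()
  if (!is.numeric(object@values) && !is.logical(object@values))
    msgs <- c(msgs, "values must be a numeric matrix")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be two finite numbers (x, y)")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@nodata) != 1L)
    msgs <- c(msgs, "nodata must be a single value")
  if (length(object@crsTag) != 1L)
    msgs <- c(msgs, "crsTag must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Threshold-envelope specification
#'
#' An ordered list of per-variable suitability conditions. A cell is suitable
#' iff every condition holds; comparisons on continuous variables are
#' inclusive at both ends. Three kinds are supported: \code{interval}
#' (min <= x <= max), \code{lower_bound} (x >= min) and \code{category_set}
#' (class membership for categorical layers).
#'
#' @slot conditions list of condition lists, each with elements
#'   \code{variable}, \code{kind} and the kind's parameters.
#' @export
setClass("EnvelopeSpec", representation(conditions = "list"))

setValidity("EnvelopeSpec", function(object) {
  msgs <- character()
  for (cond in object@conditions) {
    if (!all(c("variable", "kind") %in% names(cond))) {
      msgs <- c(msgs, "each condition needs 'variable' and 'kind'")
      next
    }
    if (cond$kind == "interval") {
      if (is.na(cond$min) || is.na(cond$max) || cond$min > cond$max)
        msgs <- c(msgs, sprintf("interval for '%s' must have min <= max",
                                cond$variable))
    } else if (cond$kind == "lower_bound") {
      if (is.na(cond$min))
        msgs <- c(msgs, sprintf("lower bound for '%s' must be finite",
                                cond$variable))
    } else if (cond$kind == "category_set") {
      if (length(cond$classes) == 0L)
        msgs <- c(msgs, sprintf("category set for '%s' must be non-empty",
                                cond$variable))
    } else {
      msgs <- c(msgs, sprintf("unknown condition kind '%s'", cond$kind))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Permutation F-test result
#'
#' @slot fObserved observed F statistic (>= 0).
#' @slot nIterations number of null draws requested.
#' @slot fNull the null distribution of F actually used.
#' @slot pValue proportion of null statistics at least as extreme as observed,
#'   under the stored comparison rule.
#' @slot seed integer seed used for Monte-Carlo resampling.
#' @slot exhaustive TRUE when all distinct label arrangements were enumerated.
#' @slot comparison "greater_equal" (default) or "greater".
#' @slot statistic "F" or "slope".
#' @slot degenerate TRUE when the response had zero variance.
#' @export
setClass("PermutationResult",
  representation(
    fObserved = "numeric", nIterations = "integer", fNull = "numeric",
    pValue = "numeric", seed = "integer", exhaustive = "logical",
    comparison = "character", statistic = "character", degenerate = "logical"
  )
)

setValidity("PermutationResult", function(object) {
  msgs <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (!object@exhaustive &&
      length(object@fNull) != object@nIterations)
    msgs <- c(msgs, "fNull length must equal nIterations unless exhaustive")
  if (length(msgs)) msgs else TRUE
})

#' Fitted hierarchical model
#'
#' Result of direct marginal-likelihood maximization (adaptive Gauss-Hermite
#' quadrature over the province intercept and, for the binomial family with
#' an observation-level random effect, a nested inner integral per county).
#'
#' @slot family "binomial", "poisson", "negbinomial" or "tweedie".
#' @slot coefficients fixed effects on the link scale (intercept, and the
#'   county-selection-method effect when present).
#' @slot sigmaProvince province random-intercept SD (link scale).
#' @slot sigmaOLRE observation-level random-effect SD, or NA when absent.
#' @slot dispersion NB size theta or Tweedie phi, NA otherwise.
#' @slot tweediePower Tweedie index p in (1, 2), NA otherwise.
#' @slot logLik maximized marginal log-likelihood.
#' @slot nParameters number of free parameters (fixed + variance + dispersion).
#' @slot converged optimizer convergence flag.
#' @slot quadraturePoints Gauss-Hermite nodes per integration level.
#' @slot ranefProvince conditional modes of the province intercepts.
#' @slot ranefOLRE conditional modes of the OLRE terms (length 0 if absent).
#' @slot fitted conditional fitted means given the random-effect modes.
#' @slot data the model frame used (response, trials, method, province).
#' @slot optimDetails list of optimizer diagnostics.
#' @export
setClass("ModelFit",
  representation(
    family = "character", coefficients = "numeric",
    sigmaProvince = "numeric", sigmaOLRE = "numeric",
    dispersion = "numeric", tweediePower = "numeric",
    logLik = "numeric", nParameters = "integer", converged = "logical",
    quadraturePoints = "integer",
    ranefProvince = "numeric", ranefOLRE = "numeric", fitted = "numeric",
    data = "data.frame", optimDetails = "list"
  )
)

setValidity("ModelFit", function(object) {
  msgs <- character()
  if (object@converged && !is.finite(object@logLik))
    msgs <- c(msgs, "logLik must be finite when converged")
  if (is.finite(object@sigmaProvince) && object@sigmaProvince < 0)
    msgs <- c(msgs, "sigmaProvince must be >= 0")
  if (is.finite(object@sigmaOLRE) && object@sigmaOLRE < 0)
    msgs <- c(msgs, "sigmaOLRE must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Power-analysis result
#'
#' @slot effectSizes probability-scale differences examined.
#' @slot power estimated rejection proportion per effect size.
#' @slot nReplicates simulation replicates per effect size.
#' @slot alpha nominal significance level of the likelihood-ratio test.
#' @slot config the survey configuration snapshot used for simulation.
#' @slot seed master seed.
#' @export
setClass("PowerResult",
  representation(
    effectSizes = "numeric", power = "numeric", nReplicates = "integer",
    alpha = "numeric", config = "list", seed = "integer"
  )
)

setValidity("PowerResult", function(object) {
  msgs <- character()
  if (length(object@power) != length(object@effectSizes))
    msgs <- c(msgs, "power and effectSizes lengths must match")
  if (any(object@power < 0 | object@power > 1))
    msgs <- c(msgs, "power values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})
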