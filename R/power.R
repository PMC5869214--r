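#' The reference two-arm survey design
#'
#' 95 counties spread over 15 provinces with the reference per-province
#' county counts (6, 3, 1, 4, 1, 10, 32, 3, 4, 12, 2, 3, 9, 1, 4), split
#' into 48 historical-record counties and 47 model-selected counties by
#' alternating assignment within provinces so both arms span provinces.
#'
#' @param provinceSizes counties per province
#' @param nHistorical number of counties in the historical arm
#' @return data.frame with county_id, province, selection_method
#' @export
referenceSurveyDesign <- function(provinceSizes = c(6, 3, 1, 4, 1, 10, 32, 3, 4,
                                              12, 2, 3, 9, 1, 4),
                            nHistorical = 48L) {
  nC <- sum(provinceSizes)
  if (nHistorical >= nC) stop("nHistorical must be below the county total")
  prov <- rep(paste0("P", seq_along(provinceSizes)), times = provinceSizes)
  # interleave arms within provinces, then trim to the exact arm sizes
  method <- unlist(lapply(provinceSizes, function(k) rep_len(c(1L, 0L), k)))
  excess <- sum(method) - nHistorical
  if (excess > 0) method[tail(which(method == 1L), excess)] <- 0L
  if (excess < 0) method[tail(which(method == 0L), -excess)] <- 1L
  data.frame(county_id = seq_len(nC), province = prov,
             selection_method = method)
}

#' Simulation-based power analysis for the two-arm interview survey
#'
#' For each candidate true difference in reporting probability, simulates
#' interview datasets with the survey's grouping structure
#' (\code{\link{generateInterviews}}), fits the binomial mixed model, and
#' tests the county-selection-method effect with a likelihood-ratio test.
#' Mirroring the analysis pipeline, each replicate first fits the model
#' without an OLRE; when its overdispersion ratio exceeds
#' \code{dispersionThreshold} the test is run on the OLRE model instead.
#' Power is the rejection proportion at \code{alpha}.
#'
#' @param config a \code{\link{surveyConfig}}; its \code{effectProbDiff}
#'   is overridden by each entry of \code{effectSizes}
#' @param design county/province layout with both arms (see
#'   \code{\link{referenceSurveyDesign}})
#' @param effectSizes probability-scale differences to examine
#' @param nReplicates simulated datasets per effect size (>= 50 advised)
#' @param alpha significance level of the LRT
#' @param seed master seed; every replicate seed derives from it
#' @param dispersionThreshold overdispersion ratio above which the OLRE
#'   model is used (default 2)
#' @param nAGQ quadrature nodes per fit
#' @param nStarts variance starting points per fit (1 keeps the simulation
#'   affordable; the fits are well-initialized from the GLM)
#' @return a \linkS4class{PowerResult}
#' @export
estimatePower <- function(config = surveyConfig(),
                          design = referenceSurveyDesign(),
                          effectSizes = c(0, 0.05, 0.10, 0.15),
                          nReplicates = 200L, alpha = 0.05, seed = 1L,
                          dispersionThreshold = 2, nAGQ = 15L,
                          nStarts = 1L) {
  if (length(unique(design$province)) < 2L)
    stop("design must span more than one province")
  if (length(unique(design$selection_method)) < 2L)
    stop("design must contain both county-selection arms")
  nReplicates <- as.integer(nReplicates)
  set.seed(seed)
  repSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                nReplicates * length(effectSizes)),
                     nReplicates, length(effectSizes))
  power <- numeric(length(effectSizes))
  for (ei in seq_along(effectSizes)) {
    rejections <- logical(nReplicates)
    for (r in seq_len(nReplicates)) {
      cfg <- config
      cfg$effectProbDiff <- effectSizes[ei]
      cfg$seed <- repSeeds[r, ei]
      rec <- generateInterviews(design, cfg)
      cs <- summarizeCounties(rec)
      rejections[r] <- .powerReplicateReject(cs, alpha, dispersionThreshold,
                                             nAGQ, nStarts)
    }
    power[ei] <- mean(rejections)
  }
  new("PowerResult", effectSizes = as.numeric(effectSizes), power = power,
      nReplicates = nReplicates, alpha = alpha,
      config = unclass(config), seed = as.integer(seed))
}

.powerReplicateReject <- function(cs, alpha, dispersionThreshold, nAGQ,
                                  nStarts) {
  alt0 <- fitBinomialGLMM(cs, olre = FALSE, methodEffect = TRUE,
                          nAGQ = nAGQ, nStarts = nStarts)
  useOLRE <- overdispersionRatio(alt0) > dispersionThreshold
  alt <- if (useOLRE)
    fitBinomialGLMM(cs, olre = TRUE, methodEffect = TRUE, nAGQ = nAGQ,
                    nStarts = nStarts) else alt0
  null <- fitBinomialGLMM(cs, olre = useOLRE, methodEffect = FALSE,
                          nAGQ = nAGQ, nStarts = nStarts)
  lrTest(null, alt)$p < alpha
}

setMethod("show", "PowerResult", function(object) {
  cat(sprintf("Power analysis: %d replicates per effect, alpha = %g\n",
              object@nReplicates, object@alpha))
  for (i in seq_along(object@effectSizes))
    cat(sprintf("  effect %+.3f -> power %.3f\n", object@effectSizes[i],
                object@power[i]))
  invisible(object)
})
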