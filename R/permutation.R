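#' Overall F statistic of a single binary-predictor linear model
#'
#' The regression F of \code{response ~ predictor} with a two-level
#' predictor, computed on the raw (untransformed) response; identical to the
#' two-group one-way ANOVA F. Proportion responses are deliberately not
#' logit-transformed (they typically contain many zeroes).
#'
#' @param response numeric vector (length >= 3)
#' @param predictor binary vector (0/1) of the same length, both levels
#'   present
#' @return the F statistic; when the response has zero variance, 0 with
#'   attribute \code{degenerate = TRUE}
#' @examples
#' olsFStatistic(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 8
#' @export
olsFStatistic <- function(response, predictor) {
  n <- length(response)
  if (n < 3L || length(predictor) != n)
    stop("response and predictor must have equal length >= 3")
  predictor <- as.numeric(predictor)
  k <- sum(predictor == 1)
  if (k == 0L || k == n)
    stop("predictor must contain both labels")
  sst <- sum((response - mean(response))^2)
  if (sst == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  .fFromGroupSum(sum(response[predictor == 1]), sum(response), sst, n, k)
}

# F from the group-1 sum alone: with totals fixed, the between-group sum of
# squares is a function of S1 only, which makes permutation loops O(1) per draw
.fFromGroupSum <- function(s1, s, sst, n, k) {
  ssb <- s1^2 / k + (s - s1)^2 / (n - k) - s^2 / n
  ssw <- sst - ssb
  (ssb / 1) / (ssw / (n - 2))
}

.slopeFromGroupSum <- function(s1, s, n, k) s1 / k - (s - s1) / (n - k)

#' Permutation test of the habitat--history association
#'
#' Tests whether a binary indicator (e.g. historical giant salamander
#' presence per county) predicts a continuous response (percent suitable
#' habitat) beyond chance. The null distribution is built by permuting the
#' labels without replacement, preserving the number of presence counties;
#' when the number of distinct label arrangements does not exceed
#' \code{nIterations}, all arrangements are enumerated exactly. An optional
#' with-replacement label bootstrap is available for sensitivity analysis.
#'
#' The default statistic is the model F (one-sided by construction); a
#' signed-slope statistic with a two-tailed comparison is available via
#' \code{statistic = "slope"}.
#'
#' @param response numeric vector
#' @param labels binary 0/1 vector, both labels present
#' @param nIterations Monte-Carlo iterations (default 10,000)
#' @param seed integer seed for the resampling
#' @param comparison "greater_equal" (default; ties count as extreme) or the
#'   strict "greater"
#' @param statistic "F" (default) or "slope" (two-tailed on |slope|)
#' @param bootstrapLabels resample labels with replacement instead of
#'   permuting (never exhaustive)
#' @param forceMonteCarlo skip the automatic exhaustive enumeration even
#'   when feasible (used to study Monte-Carlo convergence)
#' @return a \linkS4class{PermutationResult}
#' @examples
#' p <- permutationFTest(c(1, 2, 3, 4), c(0, 0, 1, 1), seed = 1)
#' p@pValue  # exhaustive: 2 of 6 arrangements reach F >= 8
#' @export
permutationFTest <- function(response, labels, nIterations = 10000L,
                             seed = 1L,
                             comparison = c("greater_equal", "greater"),
                             statistic = c("F", "slope"),
                             bootstrapLabels = FALSE,
                             forceMonteCarlo = FALSE) {
  comparison <- match.arg(comparison)
  statistic <- match.arg(statistic)
  fObs <- olsFStatistic(response, labels)
  degenerate <- isTRUE(attr(fObs, "degenerate"))
  n <- length(response)
  k <- sum(labels == 1)
  s <- sum(response)
  sst <- sum((response - mean(response))^2)
  nIterations <- as.integer(nIterations)

  statFromS1 <- if (statistic == "F") {
    function(s1) .fFromGroupSum(s1, s, sst, n, k)
  } else {
    function(s1) .slopeFromGroupSum(s1, s, n, k)
  }
  obs <- if (statistic == "F") as.numeric(fObs)
         else .slopeFromGroupSum(sum(response[labels == 1]), s, n, k)

  nArrange <- choose(n, k)
  exhaustive <- !bootstrapLabels && !forceMonteCarlo &&
    is.finite(nArrange) && nArrange <= nIterations
  if (degenerate) {
    null <- rep(0, if (exhaustive) nArrange else nIterations)
  } else if (exhaustive) {
    idx <- combn(n, k)
    s1 <- colSums(matrix(response[idx], nrow = k))
    null <- statFromS1(s1)
  } else {
    set.seed(seed)
    if (bootstrapLabels) {
      null <- vapply(seq_len(nIterations), function(i) {
        lab <- sample(c(0, 1), n, replace = TRUE)
        kk <- sum(lab)
        if (kk == 0L || kk == n) return(NA_real_)
        s1 <- sum(response[lab == 1])
        if (statistic == "F") .fFromGroupSum(s1, s, sst, n, kk)
        else .slopeFromGroupSum(s1, s, n, kk)
      }, 0)
      null <- null[!is.na(null)]
    } else {
      null <- vapply(seq_len(nIterations), function(i)
        statFromS1(sum(response[sample.int(n, k)])), 0)
    }
  }

  cmpVals <- if (statistic == "slope") abs(null) else null
  cmpObs <- if (statistic == "slope") abs(obs) else obs
  p <- if (comparison == "greater_equal")
    mean(cmpVals >= cmpObs - 1e-12) else mean(cmpVals > cmpObs + 1e-12)

  new("PermutationResult",
      fObserved = as.numeric(obs), nIterations = nIterations,
      fNull = as.numeric(null), pValue = p, seed = as.integer(seed),
      exhaustive = exhaustive, comparison = comparison,
      statistic = statistic, degenerate = degenerate)
}

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("Permutation test (%s statistic, %s rule)\n",
              object@statistic, object@comparison))
  cat(sprintf("  observed = %.4g, null draws = %d%s\n",
              object@fObserved, length(object@fNull),
              if (object@exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  p = %.4g\n", object@pValue))
  invisible(object)
})
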