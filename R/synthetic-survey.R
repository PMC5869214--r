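#' Interview survey generator configuration
#'
#' Defaults follow the survey design: ~30 interviews per county, a baseline
#' reporting probability of 0.45 in the model-selected arm, province-level
#' random intercepts and county-level extra-binomial noise of SD 0.5 on the
#' logit scale, and sighting ages centred on two decades ago. The arm effect
#' is specified as a difference on the probability scale and converted to
#' the logit scale at the baseline.
#'
#' @param respondentsPerCounty interviews per county (default 30)
#' @param baselineReportProb reporting probability in the reference
#'   (model-selected) arm, in (0, 1)
#' @param effectProbDiff true difference in reporting probability for the
#'   historical arm, probability scale
#' @param provinceInterceptSD SD of province random intercepts (logit scale)
#' @param countyOLRESD SD of county-level extra-binomial noise (logit scale)
#' @param yearsAgoFamily "nbinom", "poisson" or "geometric" for the true
#'   years-since-sighting distribution
#' @param yearsAgoMean mean of that distribution (years)
#' @param dateFormatMix named proportions over the four raw report formats
#'   (calendar_year, years_ago, decade, age_at_sighting); must sum to 1
#' @param seed integer seed
#' @return validated config list of class "SurveyConfig"
#' @export
surveyConfig <- function(respondentsPerCounty = 30L,
                         baselineReportProb = 0.45,
                         effectProbDiff = 0,
                         provinceInterceptSD = 0.5,
                         countyOLRESD = 0.5,
                         yearsAgoFamily = c("nbinom", "poisson", "geometric"),
                         yearsAgoMean = 20,
                         dateFormatMix = c(calendar_year = 0.4,
                                           years_ago = 0.3, decade = 0.2,
                                           age_at_sighting = 0.1),
                         seed = 1L) {
  yearsAgoFamily <- match.arg(yearsAgoFamily)
  cfg <- list(respondentsPerCounty = as.integer(respondentsPerCounty),
              baselineReportProb = baselineReportProb,
              effectProbDiff = effectProbDiff,
              provinceInterceptSD = provinceInterceptSD,
              countyOLRESD = countyOLRESD,
              yearsAgoFamily = yearsAgoFamily, yearsAgoMean = yearsAgoMean,
              dateFormatMix = dateFormatMix, seed = as.integer(seed))
  if (baselineReportProb <= 0 || baselineReportProb >= 1)
    stop("baselineReportProb must lie strictly in (0, 1)")
  p1 <- baselineReportProb + effectProbDiff
  if (p1 <= 0 || p1 >= 1)
    stop("baseline + effect must stay strictly in (0, 1)")
  if (provinceInterceptSD < 0 || countyOLRESD < 0)
    stop("random-effect SDs must be >= 0")
  need <- c("calendar_year", "years_ago", "decade", "age_at_sighting")
  if (!setequal(names(dateFormatMix), need))
    stop("dateFormatMix must name exactly the four report formats")
  if (abs(sum(dateFormatMix) - 1) > 1e-8)
    stop("dateFormatMix proportions must sum to 1")
  class(cfg) <- "SurveyConfig"
  cfg
}

#' Generate synthetic interview records
#'
#' One record per respondent. The report flag is Bernoulli with
#' logit(p) = beta0 + beta1 * method + u_province + e_county, where
#' beta0 = logit(baseline), beta1 = logit(baseline + effect) - beta0,
#' u ~ N(0, provinceInterceptSD^2) shared within province, and
#' e ~ N(0, countyOLRESD^2) per county (the extra-binomial noise an
#' observation-level random effect later absorbs). Reporters receive a true
#' years-before-interview value from the configured distribution (capped at
#' respondent age), rendered into one of four raw date formats; the decade
#' format first snaps the sighting year to a decade midpoint so the raw
#' report always decodes back to the stored truth. Truth columns and the
#' generating parameters (attribute \code{groundTruth}) are retained.
#'
#' @param counties data.frame with columns \code{county_id},
#'   \code{province} and \code{selection_method} (0 = model-selected,
#'   1 = historical)
#' @param config a \code{\link{surveyConfig}}
#' @return data.frame of interview records with a \code{groundTruth}
#'   attribute
#' @export
generateInterviews <- function(counties, config = surveyConfig()) {
  if (!inherits(config, "SurveyConfig")) config <- do.call(surveyConfig, config)
  if (is.null(counties) || nrow(counties) == 0L)
    stop("county table is empty")
  need <- c("county_id", "province", "selection_method")
  if (!all(need %in% names(counties)))
    stop("counties must carry columns: ", paste(need, collapse = ", "))
  set.seed(config$seed)

  beta0 <- qlogis(config$baselineReportProb)
  beta1 <- qlogis(config$baselineReportProb + config$effectProbDiff) - beta0
  provs <- unique(counties$province)
  u <- setNames(rnorm(length(provs), 0, config$provinceInterceptSD), provs)
  nC <- nrow(counties)
  e <- rnorm(nC, 0, config$countyOLRESD)
  pCounty <- plogis(beta0 + beta1 * counties$selection_method +
                    u[as.character(counties$province)] + e)

  nPer <- config$respondentsPerCounty
  idx <- rep(seq_len(nC), each = nPer)
  n <- nC * nPer
  interviewYear <- rep(sample(2013:2016, nC, replace = TRUE), each = nPer)
  age <- pmin(pmax(round(rnorm(n, 47, 14.6)), 15L), 89L)
  sex <- ifelse(runif(n) < 0.7, "male", "female")
  reported <- rbinom(n, 1L, pCounty[idx]) == 1L
  identified <- reported | (runif(n) < 0.85)

  trueYears <- rep(NA_integer_, n)
  rawFormat <- rep(NA_character_, n)
  rawValue <- rep(NA_character_, n)
  rep_i <- which(reported)
  if (length(rep_i)) {
    m <- config$yearsAgoMean
    draw <- switch(config$yearsAgoFamily,
      nbinom = rnbinom(length(rep_i), size = 1.5, mu = m),
      poisson = rpois(length(rep_i), m),
      geometric = rgeom(length(rep_i), 1 / (1 + m)))
    ty <- pmin(draw, age[rep_i])
    fmt <- sample(names(config$dateFormatMix), length(rep_i), replace = TRUE,
                  prob = config$dateFormatMix)
    iy <- interviewYear[rep_i]
    # decade reports: snap the true sighting year to a decade midpoint so
    # the rendered decade decodes back to the truth exactly
    isDec <- fmt == "decade"
    if (any(isDec)) {
      sy <- iy[isDec] - ty[isDec]
      mid <- floor(sy / 10) * 10 + 5
      mid <- ifelse(mid > iy[isDec], mid - 10, mid)
      tyDec <- iy[isDec] - mid
      bad <- tyDec > age[rep_i][isDec]
      fmt[isDec][bad] <- "years_ago"
      ty[isDec][!bad] <- tyDec[!bad]
    }
    val <- character(length(rep_i))
    cy <- fmt == "calendar_year"; val[cy] <- as.character(iy[cy] - ty[cy])
    ya <- fmt == "years_ago"; val[ya] <- as.character(ty[ya])
    dc <- fmt == "decade"
    val[dc] <- paste0(floor((iy[dc] - ty[dc]) / 10) * 10, "s")
    aa <- fmt == "age_at_sighting"
    val[aa] <- as.character(age[rep_i][aa] - ty[aa])
    trueYears[rep_i] <- ty
    rawFormat[rep_i] <- fmt
    rawValue[rep_i] <- val
  }

  out <- data.frame(
    respondent_id = seq_len(n),
    county_id = counties$county_id[idx],
    province = counties$province[idx],
    selection_method = counties$selection_method[idx],
    interview_year = interviewYear,
    age = age, sex = sex,
    identified_correctly = identified,
    reported_sighting = reported,
    raw_format = rawFormat, raw_value = rawValue,
    true_years_ago = trueYears,
    stringsAsFactors = FALSE
  )
  attr(out, "groundTruth") <- list(
    beta0 = beta0, beta1 = beta1, uProvince = u, eCounty = e,
    pCounty = pCounty, config = config)
  out
}
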