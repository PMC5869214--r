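#' Normalize a raw last-sighting report to years before interview
#'
#' Respondents describe past sightings in four formats; all are converted to
#' whole years before the interview:
#' \itemize{
#'   \item \code{calendar_year}: interview year minus the reported year.
#'   \item \code{years_ago}: the reported value itself.
#'   \item \code{decade} ("1980s" or 1980): interview year minus the decade
#'     midpoint (1985 for the 1980s), unbiased under a uniform-within-decade
#'     assumption; \code{decadeRule = "start"} uses the decade's first year.
#'   \item \code{age_at_sighting}: respondent age minus age at sighting.
#' }
#' A report that decodes to a sighting after the interview is a validation
#' error in the scalar form; the vectorized \code{normalizeSightingDates}
#' flags such records as missing and reports their count. Unparseable values
#' become missing with a warning.
#'
#' @param format one of "calendar_year", "years_ago", "decade",
#'   "age_at_sighting"
#' @param value the raw reported value (number or string)
#' @param interviewYear calendar year of the interview (1900--2100)
#' @param respondentAge respondent age in years (required for
#'   age_at_sighting)
#' @param decadeRule "midpoint" (default) or "start"
#' @return integer years before interview, or \code{NA} if unparseable
#' @examples
#' normalizeSightingDate("calendar_year", 2005, 2015)      # 10
#' normalizeSightingDate("decade", "1980s", 2015)          # 30
#' normalizeSightingDate("age_at_sighting", 20, 2015, 47)  # 27
#' @export
normalizeSightingDate <- function(format, value, interviewYear,
                                  respondentAge = NA,
                                  decadeRule = c("midpoint", "start")) {
  decadeRule <- match.arg(decadeRule)
  if (!is.finite(interviewYear) || interviewYear < 1900 || interviewYear > 2100)
    stop("interviewYear must be a plausible calendar year (1900-2100)")
  t <- .decodeSighting(format, value, interviewYear, respondentAge, decadeRule)
  if (is.na(t)) {
    warning("unparseable sighting report: ", deparse(value))
    return(NA_integer_)
  }
  if (t < 0)
    stop("reported sighting falls after the interview year")
  as.integer(t)
}

.decodeSighting <- function(format, value, interviewYear, respondentAge,
                            decadeRule) {
  num <- suppressWarnings(as.numeric(gsub("[sS]$", "", as.character(value))))
  switch(format,
    calendar_year = if (is.na(num)) NA_real_ else interviewYear - num,
    years_ago = num,
    decade = {
      if (is.na(num)) NA_real_
      else {
        d <- floor(num / 10) * 10
        interviewYear - (d + if (decadeRule == "midpoint") 5 else 0)
      }
    },
    age_at_sighting = {
      if (is.na(respondentAge) || respondentAge < 0)
        stop("age_at_sighting reports require a nonnegative respondent age")
      if (is.na(num)) NA_real_ else respondentAge - num
    },
    stop("unknown report format: ", format)
  )
}

#' @rdname normalizeSightingDate
#' @param records interview data.frame with columns raw_format, raw_value,
#'   interview_year, age, reported_sighting
#' @return \code{normalizeSightingDates}: the records with a
#'   \code{years_before_interview} column; attribute \code{nFlagged} counts
#'   records excluded because the sighting postdated the interview, and
#'   \code{nUnparseable} counts undecodable reports.
#' @export
normalizeSightingDates <- function(records,
                                   decadeRule = c("midpoint", "start")) {
  decadeRule <- match.arg(decadeRule)
  n <- nrow(records)
  yrs <- rep(NA_integer_, n)
  nFlagged <- 0L; nUnparseable <- 0L
  for (i in which(records$reported_sighting & !is.na(records$raw_format))) {
    t <- .decodeSighting(records$raw_format[i], records$raw_value[i],
                         records$interview_year[i], records$age[i],
                         decadeRule)
    if (is.na(t)) { nUnparseable <- nUnparseable + 1L; next }
    if (t < 0) { nFlagged <- nFlagged + 1L; next }
    yrs[i] <- as.integer(t)
  }
  records$years_before_interview <- yrs
  attr(records, "nFlagged") <- nFlagged
  attr(records, "nUnparseable") <- nUnparseable
  records
}

#' Summarize interview records per county
#'
#' Per county: respondents, reporters, reporting proportion, and the
#' recency of dated reports (minimum = most recent sighting, and the mean,
#' in years before interview). Counties with no dated reports get missing
#' recency; under the default \code{meanYearsZeroFill = TRUE} the
#' \emph{mean} response is filled with 0 so the zero-containing response
#' suits a Tweedie model, while the minimum stays missing.
#'
#' @param records interview data.frame carrying
#'   \code{years_before_interview} (see
#'   \code{\link{normalizeSightingDates}}); if absent it is computed.
#' @param meanYearsZeroFill fill mean_years_ago with 0 for counties with no
#'   dated reports (default TRUE)
#' @return data.frame with one row per county: county_id, province,
#'   selection_method, n_respondents, n_reported, proportion_reported,
#'   min_years_ago, mean_years_ago
#' @export
summarizeCounties <- function(records, meanYearsZeroFill = TRUE) {
  if (is.null(records) || nrow(records) == 0L)
    return(data.frame(county_id = integer(), province = character(),
                      selection_method = integer(),
                      n_respondents = integer(), n_reported = integer(),
                      proportion_reported = numeric(),
                      min_years_ago = numeric(), mean_years_ago = numeric()))
  if (is.null(records$years_before_interview))
    records <- normalizeSightingDates(records)
  sp <- split(records, records$county_id)
  rows <- lapply(sp, function(r) {
    dated <- r$years_before_interview[!is.na(r$years_before_interview)]
    data.frame(
      county_id = r$county_id[1], province = r$province[1],
      selection_method = r$selection_method[1],
      n_respondents = nrow(r),
      n_reported = sum(r$reported_sighting),
      proportion_reported = mean(r$reported_sighting),
      min_years_ago = if (length(dated)) min(dated) else NA_real_,
      mean_years_ago = if (length(dated)) mean(dated)
                       else if (meanYearsZeroFill) 0 else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$county_id), , drop = FALSE]
}

#' Chi-squared test on a 2 x 2 contingency table
#'
#' Pearson chi-squared with Yates continuity correction by default (1 df),
#' e.g. for comparing the number of counties yielding any sighting report
#' between the two county-selection arms.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts with positive
#'   margins
#' @param correction apply the Yates continuity correction (default TRUE)
#' @return list with elements chi2, df (= 1) and p
#' @examples
#' contingencyChi2(matrix(c(43, 40, 5, 7), 2))  # chi2 ~ 0.12, p ~ 0.73
#' @export
contingencyChi2 <- function(table, correction = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("a 2 x 2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all table margins must be positive")
  ct <- suppressWarnings(chisq.test(table, correct = correction))
  list(chi2 = unname(ct$statistic), df = 1L, p = unname(ct$p.value))
}

#' Descriptive statistics of an interview dataset
#'
#' @param records interview data.frame (with
#'   \code{years_before_interview} if dated-report counts are wanted)
#' @return list: n_respondents, n_reported, pct_reported (1 dp), n_dated,
#'   pct_dated (1 dp), interviews_per_county (mean, min, max, sd), age
#'   (mean, sd), sex_proportions
#' @export
datasetDescriptives <- function(records) {
  n <- nrow(records)
  nRep <- sum(records$reported_sighting)
  nDated <- if (!is.null(records$years_before_interview))
    sum(!is.na(records$years_before_interview)) else NA_integer_
  perCounty <- as.vector(table(records$county_id))
  sexTab <- table(records$sex)
  list(
    n_respondents = n,
    n_reported = nRep,
    pct_reported = round(100 * nRep / n, 1),
    n_dated = nDated,
    pct_dated = if (is.na(nDated)) NA_real_ else round(100 * nDated / n, 1),
    interviews_per_county = c(mean = mean(perCounty), min = min(perCounty),
                              max = max(perCounty), sd = sd(perCounty)),
    age = c(mean = mean(records$age), sd = sd(records$age)),
    sex_proportions = round(as.vector(sexTab) / n, 3) |>
      setNames(names(sexTab))
  )
}
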