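#' Default pipeline configuration
#'
#' Returns the bundled configuration list (also shipped as
#' \code{inst/extdata/default_config.yaml}). Sizes are chosen so the whole
#' synthetic analysis completes in minutes on one core while exercising
#' every stage.
#'
#' @param seed master seed applied to every stochastic stage
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    landscape = list(gridRows = 80L, gridCols = 80L, nCounties = 60L,
                     nProvinces = 8L, autocorrelationLength = 8L),
    envelope = list(forestClasses = 1L, precipMode = "sum"),
    historical = list(intercept = -2.5, slopePerPercent = 0.1),
    randomization = list(nIterations = 10000L),
    survey = list(respondentsPerCounty = 30L, baselineReportProb = 0.45,
                  effectProbDiff = 0, provinceInterceptSD = 0.5,
                  countyOLRESD = 0.5, countiesPerArm = 12L),
    power = list(effectSizes = c(0, 0.10), nReplicates = 20L, alpha = 0.05)
  )
}

.mergeConfig <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], extra[[nm]])
    else base[[nm]] <- extra[[nm]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file keep their defaults.
#'
#' @param path YAML file
#' @return configuration list
#' @export
readPipelineConfig <- function(path) {
  .mergeConfig(defaultPipelineConfig(), yaml::read_yaml(path))
}

.stage <- function(name, expr, verbose) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic analysis end-to-end
#'
#' simulate -> suitability -> zonal -> randomization test -> interview
#' statistics -> model battery -> power, writing county and interview CSVs,
#' the suitability raster (ESRI ASCII grid), a ground-truth JSON sidecar, a
#' results JSON and a human-readable report to \code{outdir}. Every
#' stochastic stage derives its seed from the configured master seed, so a
#' given config produces byte-identical outputs on re-run.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or path to a YAML file
#' @param outdir output directory, created if missing
#' @param seed optional master-seed override
#' @param verbose print stage progress
#' @return (invisibly) list with all stage results
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir = "pipeline_out",
                        seed = NULL, verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- .mergeConfig(defaultPipelineConfig(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  masterSeed <- config$seed
  stageSeed <- function(k) (masterSeed + 7919L * k) %% .Machine$integer.max

  land <- .stage("simulate", {
    lcfg <- do.call(landscapeConfig,
                    c(config$landscape, list(seed = stageSeed(1L))))
    generateLandscape(lcfg)
  }, verbose)

  suit <- .stage("suitability", {
    tAnn <- aggregateClimate(land$monthlyTemperature, "mean")
    precipMode <- config$envelope$precipMode %||% "sum"
    pAnn <- switch(precipMode,
      sum = aggregateClimate(land$monthlyPrecipitation, "sum"),
      mean_x12 = setGridValues(
        aggregateClimate(land$monthlyPrecipitation, "mean"),
        gridValues(aggregateClimate(land$monthlyPrecipitation, "mean")) * 12),
      mean = aggregateClimate(land$monthlyPrecipitation, "mean"))
    forest <- regroupLandcover(land$landcover, config$envelope$forestClasses)
    applyEnvelope(list(elevation = land$elevation, temperature = tAnn,
                       precipitation = pAnn, landcover = forest),
                  giantSalamanderEnvelope(1L))
  }, verbose)

  zonal <- .stage("zonal", {
    zt <- percentSuitableByZone(suit, land$countyLabels)
    merge(data.frame(county_id = land$countyProvince$county_id,
                     province = land$countyProvince$province),
          data.frame(county_id = zt$zone_id, n_cells = zt$n_cells,
                     n_suitable = zt$n_suitable,
                     percent_suitable = zt$percent_suitable),
          by = "county_id", all.x = TRUE)
  }, verbose)

  hist <- .stage("historical", {
    generateHistoricalRecords(zonal, config$historical$intercept,
                              config$historical$slopePerPercent,
                              seed = stageSeed(2L))
  }, verbose)

  randtest <- .stage("randtest", {
    permutationFTest(hist$percent_suitable, hist$presence,
                     nIterations = config$randomization$nIterations,
                     seed = stageSeed(3L))
  }, verbose)

  interviews <- .stage("interviews", {
    nArm <- config$survey$countiesPerArm
    histIdx <- which(hist$presence == 1L)
    modIdx <- setdiff(order(hist$percent_suitable, decreasing = TRUE),
                      histIdx)
    set.seed(stageSeed(4L))
    armH <- if (length(histIdx) > nArm) sort(sample(histIdx, nArm)) else histIdx
    armM <- head(modIdx, nArm)
    if (length(armH) < 2L || length(armM) < 2L)
      stop("fewer than 2 counties available in a survey arm; ",
           "increase the landscape size or adjust the historical-record model")
    design <- rbind(
      data.frame(county_id = hist$county_id[armH],
                 province = hist$province[armH], selection_method = 1L),
      data.frame(county_id = hist$county_id[armM],
                 province = hist$province[armM], selection_method = 0L))
    scfg <- do.call(surveyConfig, c(
      config$survey[setdiff(names(config$survey), "countiesPerArm")],
      list(seed = stageSeed(5L))))
    rec <- generateInterviews(design, scfg)
    rec <- normalizeSightingDates(rec)
    cs <- summarizeCounties(rec)
    anyReport <- tapply(rec$reported_sighting, rec$county_id, any)
    arm <- cs$selection_method[match(names(anyReport), cs$county_id)]
    tab <- rbind(c(sum(anyReport & arm == 1L), sum(!anyReport & arm == 1L)),
                 c(sum(anyReport & arm == 0L), sum(!anyReport & arm == 0L)))
    chi2 <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      NULL else contingencyChi2(tab)
    list(records = rec, summaries = cs, design = design,
         descriptives = datasetDescriptives(rec), reportTable = tab,
         chi2 = chi2)
  }, verbose)

  models <- .stage("models", {
    cs <- interviews$summaries
    binom0 <- fitBinomialGLMM(cs, olre = FALSE)
    disp <- overdispersionRatio(binom0)
    useOLRE <- disp > 2
    binom <- if (useOLRE) fitBinomialGLMM(cs, olre = TRUE) else binom0
    binomNull <- fitBinomialGLMM(cs, olre = useOLRE, methodEffect = FALSE)
    binomLRT <- lrTest(binomNull, binom)
    olreLRT <- if (useOLRE) lrTest(binom0, binom) else NULL
    pois <- fitCountGLMM(cs, "min_years_ago", "poisson")
    poisDisp <- overdispersionRatio(pois)
    nb <- fitCountGLMM(cs, "min_years_ago", "negbinomial")
    nbLRT <- lrTest(pois, nb)
    nbNull <- fitCountGLMM(cs, "min_years_ago", "negbinomial",
                           methodEffect = FALSE)
    tw <- fitTweedieGLMM(cs, "mean_years_ago")
    twNull <- fitTweedieGLMM(cs, "mean_years_ago", methodEffect = FALSE)
    list(binomial = binom, binomialDispersion = disp, olreUsed = useOLRE,
         binomialMethodLRT = binomLRT, olreLRT = olreLRT,
         poisson = pois, poissonDispersion = poisDisp, negbinomial = nb,
         nbVsPoissonLRT = nbLRT,
         nbMethodLRT = lrTest(nbNull, nb),
         tweedie = tw, tweedieMethodLRT = lrTest(twNull, tw))
  }, verbose)

  power <- .stage("power", {
    scfg <- do.call(surveyConfig, c(
      config$survey[setdiff(names(config$survey), "countiesPerArm")],
      list(seed = stageSeed(6L))))
    estimatePower(scfg, design = referenceSurveyDesign(),
                  effectSizes = config$power$effectSizes,
                  nReplicates = config$power$nReplicates,
                  alpha = config$power$alpha, seed = stageSeed(6L))
  }, verbose)

  .stage("write", {
    writeAsciiGrid(suit, file.path(outdir, "suitability.asc"))
    writeAsciiGrid(land$countyLabels, file.path(outdir, "county_labels.asc"))
    write.csv(hist, file.path(outdir, "counties.csv"), row.names = FALSE)
    write.csv(interviews$records, file.path(outdir, "interviews.csv"),
              row.names = FALSE)
    gt <- attr(interviews$records, "groundTruth")
    jsonlite::write_json(list(
      historical = attr(hist, "groundTruth")[c("intercept",
                                               "slopePerPercent", "seed")],
      survey = list(beta0 = gt$beta0, beta1 = gt$beta1,
                    config = unclass(gt$config))),
      file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    results <- .pipelineResults(config, zonal, randtest, interviews, models,
                                power)
    jsonlite::write_json(results, file.path(outdir, "results.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(.pipelineReport(results), file.path(outdir, "report.txt"))
  }, verbose)

  invisible(list(config = config, landscape = land, suitability = suit,
                 counties = hist, randtest = randtest,
                 interviews = interviews, models = models, power = power))
}

.pipelineResults <- function(config, zonal, randtest, interviews, models,
                             power) {
  desc <- interviews$descriptives
  list(
    seed = config$seed,
    zonal = list(n_counties = nrow(zonal),
                 mean_percent_suitable = mean(zonal$percent_suitable,
                                              na.rm = TRUE)),
    randomization = list(f_observed = randtest@fObserved,
                         p_value = randtest@pValue,
                         n_iterations = length(randtest@fNull),
                         exhaustive = randtest@exhaustive,
                         seed = randtest@seed),
    interviews = list(n_respondents = desc$n_respondents,
                      pct_reported = desc$pct_reported,
                      pct_dated = desc$pct_dated,
                      chi2 = interviews$chi2),
    models = list(
      binomial = .fitSummary(models$binomial),
      binomial_dispersion_no_olre = models$binomialDispersion,
      olre_used = models$olreUsed,
      binomial_method_lrt = models$binomialMethodLRT,
      olre_lrt = models$olreLRT,
      poisson_dispersion = models$poissonDispersion,
      negbinomial = .fitSummary(models$negbinomial),
      nb_vs_poisson_lrt = models$nbVsPoissonLRT,
      nb_method_lrt = models$nbMethodLRT,
      tweedie = .fitSummary(models$tweedie),
      tweedie_method_lrt = models$tweedieMethodLRT),
    power = list(effect_sizes = power@effectSizes, power = power@power,
                 n_replicates = power@nReplicates, alpha = power@alpha,
                 seed = power@seed),
    verification = .verificationBlock(power)
  )
}

.fitSummary <- function(fit) {
  list(coefficients = as.list(fit@coefficients),
       sigma_province = fit@sigmaProvince,
       sigma_olre = if (is.finite(fit@sigmaOLRE)) fit@sigmaOLRE else NULL,
       dispersion = if (is.finite(fit@dispersion)) fit@dispersion else NULL,
       tweedie_power = if (is.finite(fit@tweediePower)) fit@tweediePower
                       else NULL,
       log_lik = fit@logLik, converged = fit@converged)
}

# the six benchmark statistics: five arithmetic identities recomputable
# from published counts, plus the power claim at the configured scale
.verificationBlock <- function(power) {
  chi <- contingencyChi2(matrix(c(43, 40, 5, 7), 2))
  i10 <- which(abs(power@effectSizes - 0.10) < 1e-9)
  powerAt10 <- if (length(i10)) power@power[i10[1]] else NA_real_
  list(
    chi2_counties_with_reports = list(value = round(chi$chi2, 2),
                                      expected = 0.12,
                                      pass = round(chi$chi2, 2) == 0.12),
    pct_reported = list(value = round(100 * 1299 / 2812, 1),
                        expected = 46.2,
                        pass = round(100 * 1299 / 2812, 1) == 46.2),
    pct_dated = list(value = round(100 * 1146 / 2812, 1), expected = 40.8,
                     pass = round(100 * 1146 / 2812, 1) == 40.8),
    pct_counties_historical = list(value = round(100 * 145 / 2852, 1),
                                   expected = 5.1,
                                   pass = round(100 * 145 / 2852, 1) == 5.1),
    pct_counties_suitable = list(value = round(100 * 156 / 2852, 1),
                                 expected = 5.5,
                                 pass = round(100 * 156 / 2852, 1) == 5.5),
    power_at_10pct = list(value = powerAt10, expected = ">= 0.80",
                          pass = isTRUE(powerAt10 >= 0.80),
                          note = sprintf("%d replicates at this run's scale",
                                         power@nReplicates))
  )
}

.pipelineReport <- function(res) {
  fmt <- function(x, d = 4) formatC(x, digits = d, format = "g")
  lines <- c(
    "Synthetic limited-data prioritization analysis",
    sprintf("master seed: %d", res$seed),
    "",
    sprintf("Counties: %d; mean percent suitable habitat: %s",
            res$zonal$n_counties, fmt(res$zonal$mean_percent_suitable)),
    sprintf("Randomization test: F = %s, p = %s (%d iterations%s, seed %d)",
            fmt(res$randomization$f_observed), fmt(res$randomization$p_value),
            res$randomization$n_iterations,
            if (res$randomization$exhaustive) ", exhaustive" else "",
            res$randomization$seed),
    "",
    sprintf("Interviews: %d respondents; %.1f%% reported sightings, %.1f%% dated",
            res$interviews$n_respondents, res$interviews$pct_reported,
            res$interviews$pct_dated),
    if (!is.null(res$interviews$chi2))
      sprintf("Counties-with-reports chi-squared: chi2 = %s, p = %s",
              fmt(res$interviews$chi2$chi2), fmt(res$interviews$chi2$p))
    else "Counties-with-reports chi-squared: not defined (degenerate margin)",
    "",
    sprintf("Binomial GLMM: dispersion (no OLRE) = %s; OLRE used: %s",
            fmt(res$models$binomial_dispersion_no_olre),
            res$models$olre_used),
    sprintf("  method effect LRT: chi2 = %s, df = %d, p = %s",
            fmt(res$models$binomial_method_lrt$chi2),
            res$models$binomial_method_lrt$df,
            fmt(res$models$binomial_method_lrt$p)),
    sprintf("NB vs Poisson LRT: chi2 = %s, p = %s",
            fmt(res$models$nb_vs_poisson_lrt$chi2),
            fmt(res$models$nb_vs_poisson_lrt$p)),
    sprintf("Tweedie method LRT: chi2 = %s, p = %s (p-hat = %s)",
            fmt(res$models$tweedie_method_lrt$chi2),
            fmt(res$models$tweedie_method_lrt$p),
            fmt(res$models$tweedie$tweedie_power)),
    "",
    sprintf("Power (%d replicates): %s", res$power$n_replicates,
            paste(sprintf("%.0f%% @ effect %.2f", 100 * res$power$power,
                          res$power$effect_sizes), collapse = ", ")),
    "",
    "Benchmark statistics:"
  )
  for (nm in names(res$verification)) {
    v <- res$verification[[nm]]
    lines <- c(lines, sprintf("  [%s] %-28s value = %s (expected %s)",
                              if (isTRUE(v$pass)) "PASS" else "FAIL", nm,
                              fmt(unlist(v$value)),
                              paste(v$expected, collapse = " ")))
  }
  lines
}
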