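test_that("binomial province model agrees with an independent AGQ fitter", {
  cs <- makeBinomialCounties(12L, 6L, n = 30L, beta0 = 0.1, beta1 = 0.5,
                             sigmaP = 0.6, seed = 4L)
  ours <- fitBinomialGLMM(cs, olre = FALSE, nStarts = 1L)
  ref <- lme4::glmer(
    cbind(n_reported, n_respondents - n_reported) ~ selection_method +
      (1 | province),
    data = cs, family = binomial(), nAGQ = 15)
  expect_equal(unname(ours@coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(ours@sigmaProvince,
               sqrt(unlist(lme4::VarCorr(ref))[[1]]), tolerance = 1e-3)
  # absolute log-likelihoods differ by lme4's saturated-model constant,
  # which cancels in the likelihood-ratio statistic for the method effect
  ours0 <- fitBinomialGLMM(cs, olre = FALSE, methodEffect = FALSE,
                           nStarts = 1L)
  ref0 <- lme4::glmer(
    cbind(n_reported, n_respondents - n_reported) ~ (1 | province),
    data = cs, family = binomial(), nAGQ = 15)
  expect_equal(2 * (ours@logLik - ours0@logLik),
               2 * (as.numeric(logLik(ref)) - as.numeric(logLik(ref0))),
               tolerance = 1e-3)
})

test_that("data with no province variation stay close to plain logistic regression", {
  # finite samples leave a small positive sigma-hat, so the mixed fit can
  # only sit (slightly) above the nested GLM; exact boundary equality of
  # the quadrature engine is checked separately at fixed parameters
  cs <- makeBinomialCounties(8L, 8L, beta0 = -0.2, beta1 = 0.6,
                             sigmaP = 0, seed = 2L)
  ours <- fitBinomialGLMM(cs, olre = FALSE)
  ref <- glm(cbind(n_reported, n_respondents - n_reported) ~
               selection_method, data = cs, family = binomial())
  expect_lt(ours@sigmaProvince, 0.25)
  expect_gte(ours@logLik, as.numeric(logLik(ref)) - 1e-6)
  expect_lt(ours@logLik - as.numeric(logLik(ref)), 2)
  expect_equal(unname(ours@coefficients), unname(coef(ref)),
               tolerance = 0.05)
})

test_that("binomial GLMM recovers an injected method effect", {
  est <- vapply(1:12, function(i) {
    cs <- makeBinomialCounties(25L, 6L, n = 30L, beta0 = 0, beta1 = 1,
                               sigmaP = 0.5, seed = 100L + i)
    fitBinomialGLMM(cs, olre = FALSE, nStarts = 1L)@coefficients[["method"]]
  }, 0)
  expect_lt(abs(mean(est) - 1), 0.1)
})

test_that("the OLRE absorbs extra-binomial noise and improves the fit", {
  cs <- makeBinomialCounties(10L, 10L, n = 40L, beta0 = 0, beta1 = 0.3,
                             sigmaP = 0.4, sigmaE = 1, seed = 8L)
  plain <- fitBinomialGLMM(cs, olre = FALSE, nStarts = 1L)
  olre <- fitBinomialGLMM(cs, olre = TRUE, nStarts = 1L)
  expect_gt(overdispersionRatio(plain), 3)
  expect_lt(overdispersionRatio(olre), 1.5)
  expect_gte(olre@logLik, plain@logLik - 1e-6)  # extra parameter never hurts
  lrt <- lrTest(plain, olre)
  expect_identical(lrt$df, 1L)
  expect_lt(lrt$p, 0.001)
  expect_gt(olre@sigmaOLRE, 0.6)
  expect_lt(olre@sigmaOLRE, 1.4)
})

test_that("negative binomial nests Poisson and recovers its size parameter", {
  cs <- makeCountCounties(10L, 8L, family = "poisson", seed = 3L)
  pois <- fitCountGLMM(cs, family = "poisson", nStarts = 1L)
  nbBig <- fitCountGLMM(cs, family = "negbinomial", thetaFixed = 1e6,
                        nStarts = 1L)
  expect_equal(nbBig@logLik, pois@logLik, tolerance = 1e-4)
  expect_identical(nbBig@nParameters, pois@nParameters)

  # Poisson fit is well-calibrated on Poisson data ...
  big <- makeCountCounties(10L, 50L, family = "poisson", seed = 5L)
  disp <- overdispersionRatio(fitCountGLMM(big, family = "poisson",
                                           nStarts = 1L))
  expect_gt(disp, 0.8); expect_lt(disp, 1.2)

  # ... and flags strong overdispersion on NB data
  nbData <- makeCountCounties(10L, 10L, family = "negbinomial",
                              theta = 0.5, seed = 6L)
  expect_gt(overdispersionRatio(fitCountGLMM(nbData, family = "poisson",
                                             nStarts = 1L)), 3)

  thetaHat <- vapply(1:5, function(i) {
    d <- makeCountCounties(15L, 20L, family = "negbinomial", theta = 2,
                           seed = 500L + i)
    fitCountGLMM(d, family = "negbinomial", nStarts = 1L)@dispersion
  }, 0)
  expect_true(all(thetaHat > 1.5 & thetaHat < 2.7))
})

test_that("NB mixed fit matches an independent mixed-model implementation", {
  d <- makeCountCounties(15L, 20L, family = "negbinomial", theta = 2,
                         seed = 501L)
  ours <- fitCountGLMM(d, family = "negbinomial", nStarts = 1L)
  ref <- glmmTMB::glmmTMB(min_years_ago ~ selection_method + (1 | province),
                          family = glmmTMB::nbinom2, data = d)
  expect_equal(unname(ours@coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 0.02)
  expect_equal(ours@dispersion, glmmTMB::sigma(ref), tolerance = 0.05)
})

test_that("count model input validation", {
  cs <- makeCountCounties(4L, 4L, seed = 1L)
  cs$min_years_ago[2] <- 2.5
  expect_error(fitCountGLMM(cs, family = "poisson"), "integers")
  one <- makeCountCounties(4L, 4L, seed = 1L)
  one$province <- "P1"
  expect_error(fitCountGLMM(one, family = "poisson"), "provinces")
})

test_that("quadrature is converged by 15 nodes", {
  cs <- makeBinomialCounties(8L, 6L, beta0 = 0, beta1 = 0.5, sigmaP = 0.7,
                             seed = 12L)
  f15 <- fitBinomialGLMM(cs, olre = FALSE, nAGQ = 15L, nStarts = 1L)
  f25 <- fitBinomialGLMM(cs, olre = FALSE, nAGQ = 25L, nStarts = 1L)
  expect_equal(f15@coefficients, f25@coefficients, tolerance = 1e-3)
  expect_equal(f15@sigmaProvince, f25@sigmaProvince, tolerance = 1e-3)
  expect_equal(f15@logLik, f25@logLik, tolerance = 1e-3)
})

test_that("likelihood-ratio test arithmetic and guards", {
  mkFit <- function(ll, k) new("ModelFit", family = "binomial",
    coefficients = c("(Intercept)" = 0), sigmaProvince = 0.1,
    sigmaOLRE = NA_real_, dispersion = NA_real_, tweediePower = NA_real_,
    logLik = ll, nParameters = as.integer(k), converged = TRUE,
    quadraturePoints = 15L, ranefProvince = numeric(), ranefOLRE = numeric(),
    fitted = numeric(), data = data.frame(), optimDetails = list())

  same <- lrTest(mkFit(-100, 2), mkFit(-100, 3))
  expect_equal(same$chi2, 0); expect_equal(same$p, 1)

  lrt <- lrTest(mkFit(-100, 2), mkFit(-97, 3))
  expect_equal(lrt$chi2, 6)
  expect_equal(lrt$p, pchisq(6, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(lrt$p, 4), 0.0143)
  expect_lt(lrt$pBoundary, lrt$p)

  expect_warning(clamped <- lrTest(mkFit(-97, 2), mkFit(-97.5, 3)),
                 "clamping")
  expect_equal(clamped$chi2, 0)
  expect_error(lrTest(mkFit(-97, 3), mkFit(-100, 3)), "nested")
})

test_that("the dispersion ratio is Pearson chi-squared over residual df", {
  expect_equal(overdispersionRatio(c(1, -1, 1, -1), df = 2), 2)
  expect_error(overdispersionRatio(c(1, -1), df = 0), "positive")
})
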