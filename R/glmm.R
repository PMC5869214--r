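# Marginal-likelihood machinery for the hierarchical model battery.
#
# All models share one structure: a county-level response with fixed effects
# (intercept + county-selection method), a province random intercept
# integrated out by adaptive Gauss-Hermite quadrature (AGQ), and - for the
# binomial family - an optional observation-level random effect (OLRE)
# handled by a nested inner AGQ per county. Provinces often contain few
# counties, where a Laplace-only approximation is least accurate; AGQ with
# 15 nodes per level is the default throughout.

.ghCache <- new.env(parent = emptyenv())

# Gauss-Hermite rule for integrals against exp(-x^2); logw already folds in
# the exp(z^2) factor of the adaptive formulation
.ghRule <- function(k) {
  key <- as.character(k)
  if (is.null(.ghCache[[key]])) {
    r <- pracma::gaussHermite(k)
    .ghCache[[key]] <- list(z = r$x, logw = log(r$w) + r$x^2)
  }
  .ghCache[[key]]
}

.logSumExpRows <- function(M) {
  m <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) m <- pmax(m, M[, j])
  m0 <- ifelse(is.finite(m), m, 0)
  m0 + log(rowSums(exp(M - m0)))
}

# inner integral for the binomial + OLRE model: given a matrix A = eta + u
# (counties x outer nodes), integrate the county-level extra-binomial
# deviate e ~ N(0, sigmaE^2) out of Binom(y | n, plogis(A + e)).
# The integrand is log-concave, so undamped Newton from 0 finds the mode.
.innerBinomOLRE <- function(y, n, A, sigmaE, rule) {
  C <- length(y)
  E <- matrix(0, C, ncol(A))
  invVar <- 1 / sigmaE^2
  for (it in 1:40) {
    p <- plogis(A + E)
    grad <- y - n * p - E * invVar
    hess <- -(n * p * (1 - p) + invVar)
    step <- grad / hess
    step <- pmin(pmax(step, -4), 4)
    E <- E - step
    if (max(abs(step)) < 1e-9) break
  }
  p <- plogis(A + E)
  s <- 1 / sqrt(n * p * (1 - p) + invVar)
  parts <- vector("list", length(rule$z))
  for (j in seq_along(rule$z)) {
    ej <- E + sqrt(2) * s * rule$z[j]
    lp <- matrix(dbinom(y, n, plogis(A + ej), log = TRUE), C) +
      dnorm(ej, 0, sigmaE, log = TRUE) + rule$logw[j]
    parts[[j]] <- lp
  }
  m <- Reduce(pmax, parts)
  m0 <- ifelse(is.finite(m), m, 0)
  acc <- Reduce(`+`, lapply(parts, function(lp) exp(lp - m0)))
  m0 + log(acc) + 0.5 * log(2) + log(s)
}

# marginal log-likelihood: AGQ over the province intercepts. condLogG(A)
# must return the per-county conditional log-density (counties x nodes)
# given the linear predictor A = eta + u. Province modes are located by
# Newton on a central-difference stencil, vectorized across provinces.
.agqMarginal <- function(eta, provIdx, nProv, sigmaP, condLogG, rule,
                         uStart = NULL) {
  u <- if (is.null(uStart) || length(uStart) != nProv) rep(0, nProv)
       else uStart
  delta <- max(1e-6, min(1e-3, sigmaP / 20))
  hess <- rep(-1, nProv)
  for (it in 1:30) {
    U3 <- cbind(u - delta, u, u + delta)
    A <- eta + U3[provIdx, , drop = FALSE]
    S <- rowsum(condLogG(A), provIdx) + dnorm(U3, 0, sigmaP, log = TRUE)
    grad <- (S[, 3] - S[, 1]) / (2 * delta)
    hess <- pmin((S[, 3] - 2 * S[, 2] + S[, 1]) / delta^2, -1e-8)
    step <- pmin(pmax(grad / hess, -2), 2)
    u <- u - step
    if (max(abs(step)) < 1e-8) break
  }
  s <- 1 / sqrt(-hess)
  U <- u + sqrt(2) * outer(s, rule$z)
  A <- eta + U[provIdx, , drop = FALSE]
  S <- rowsum(condLogG(A), provIdx) + dnorm(U, 0, sigmaP, log = TRUE)
  M <- sweep(S, 2, rule$logw, `+`)
  ll <- .logSumExpRows(M) + 0.5 * log(2) + log(s)
  list(logLik = sum(ll), modes = u, scales = s)
}

.SIGMA_MIN <- 1e-6
.SIGMA_REPORT_ZERO <- 1e-4

# run nlminb from several variance starting points, keep the best optimum
.optimizeMarginal <- function(negll, betaInit, nSigma, nExtra = 0,
                              extraInit = numeric(), nStarts = 3L,
                              sigmaStarts = c(0.3, 1, 0.03)) {
  nBeta <- length(betaInit)
  lower <- c(rep(-Inf, nBeta), rep(log(.SIGMA_MIN), nSigma),
             rep(-Inf, nExtra))
  upper <- c(rep(Inf, nBeta), rep(log(30), nSigma), rep(Inf, nExtra))
  best <- NULL
  for (sgm in sigmaStarts[seq_len(min(nStarts, length(sigmaStarts)))]) {
    par0 <- c(betaInit, rep(log(sgm), nSigma), extraInit)
    fit <- tryCatch(
      nlminb(par0, negll, lower = lower, upper = upper,
             control = list(iter.max = 400, eval.max = 800)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$objective) &&
        (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best))
    best <- list(par = c(betaInit, rep(log(0.3), nSigma), extraInit),
                 objective = Inf, convergence = 1L,
                 message = "all starts failed")
  best
}

.coefNames <- function(methodEffect)
  if (methodEffect) c("(Intercept)", "method") else "(Intercept)"

.modelFrame <- function(counties, responseCol, trialsCol = NULL) {
  need <- c(responseCol, trialsCol, "selection_method", "province")
  miss <- setdiff(need, names(counties))
  if (length(miss))
    stop("county table lacks column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(y = counties[[responseCol]],
                   n = if (is.null(trialsCol)) NA_real_
                       else counties[[trialsCol]],
                   method = counties$selection_method,
                   province = as.character(counties$province),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$y), , drop = FALSE]
  if (length(unique(df$province)) < 2L)
    stop("at least 2 provinces are required for the province random intercept")
  df
}

#' Fit the binomial mixed model for county reporting proportions
#'
#' Maximizes the exact marginal likelihood of a binomial GLMM with county
#' selection method as a fixed effect and province as a random intercept,
#' optionally adding an observation-level random effect (OLRE) to absorb
#' extra-binomial variation. Integration is by nested adaptive
#' Gauss-Hermite quadrature: an outer 1-D integral per province and, with
#' the OLRE, an inner 1-D integral per county (counties are conditionally
#' independent given the province effect). Variance components are
#' optimized on the log-SD scale from several starting points to avoid
#' boundary local optima; SD estimates below 1e-4 are reported as 0.
#'
#' @param counties county summary data.frame with columns
#'   \code{n_reported}, \code{n_respondents}, \code{selection_method},
#'   \code{province} (see \code{\link{summarizeCounties}})
#' @param olre include the observation-level random effect
#' @param methodEffect include the county-selection-method fixed effect
#'   (FALSE gives the null model for a likelihood-ratio test)
#' @param nAGQ quadrature nodes per integration level (default 15)
#' @param nStarts number of variance starting points (default 3)
#' @return a \linkS4class{ModelFit}
#' @export
fitBinomialGLMM <- function(counties, olre = FALSE, methodEffect = TRUE,
                            nAGQ = 15L, nStarts = 3L) {
  df <- .modelFrame(counties, "n_reported", "n_respondents")
  y <- df$y; n <- df$n; x <- df$method
  if (any(y > n)) stop("n_reported exceeds n_respondents")
  provIdx <- as.integer(factor(df$province))
  nProv <- max(provIdx)
  rule <- .ghRule(nAGQ)

  nFix <- if (methodEffect) 2L else 1L
  init <- tryCatch({
    if (methodEffect) coef(glm(cbind(y, n - y) ~ x, family = binomial()))
    else coef(glm(cbind(y, n - y) ~ 1, family = binomial()))
  }, error = function(e) rep(0, nFix))
  init <- unname(init[seq_len(nFix)])
  mEnv <- new.env(parent = emptyenv()); mEnv$u <- NULL

  negll <- function(par) {
    beta0 <- par[1]; beta1 <- if (methodEffect) par[2] else 0
    sigmaP <- exp(par[nFix + 1])
    eta <- beta0 + beta1 * x
    cond <- if (olre) {
      sigmaE <- exp(par[nFix + 2])
      function(A) .innerBinomOLRE(y, n, A, sigmaE, rule)
    } else {
      function(A) matrix(dbinom(y, n, plogis(A), log = TRUE), length(y))
    }
    r <- tryCatch(.agqMarginal(eta, provIdx, nProv, sigmaP, cond, rule,
                               mEnv$u),
                  error = function(e) NULL)
    if (is.null(r) || !is.finite(r$logLik)) return(1e10)
    mEnv$u <- r$modes
    -r$logLik
  }

  opt <- .optimizeMarginal(negll, init, nSigma = if (olre) 2L else 1L,
                           nStarts = nStarts)
  par <- opt$par
  beta <- setNames(par[seq_len(nFix)], .coefNames(methodEffect))
  sigmaP <- exp(par[nFix + 1])
  sigmaE <- if (olre) exp(par[nFix + 2]) else NA_real_

  # conditional modes and fitted values at the optimum
  eta <- beta[1] + (if (methodEffect) beta[2] else 0) * x
  cond <- if (olre) function(A) .innerBinomOLRE(y, n, A, sigmaE, rule)
          else function(A) matrix(dbinom(y, n, plogis(A), log = TRUE),
                                  length(y))
  fin <- .agqMarginal(eta, provIdx, nProv, sigmaP, cond, rule, mEnv$u)
  uHat <- fin$modes
  eHat <- if (olre)
    .olreModes(y, n, eta + uHat[provIdx], sigmaE) else numeric(0)
  pHat <- plogis(eta + uHat[provIdx] + if (olre) eHat else 0)
  pearson <- (y - n * pHat) / sqrt(pmax(n * pHat * (1 - pHat), 1e-12))

  new("ModelFit",
      family = "binomial", coefficients = beta,
      sigmaProvince = if (sigmaP < .SIGMA_REPORT_ZERO) 0 else sigmaP,
      sigmaOLRE = if (olre && sigmaE < .SIGMA_REPORT_ZERO) 0 else sigmaE,
      dispersion = NA_real_, tweediePower = NA_real_,
      logLik = -opt$objective,
      nParameters = nFix + 1L + as.integer(olre),
      converged = is.finite(opt$objective) && opt$convergence == 0L,
      quadraturePoints = as.integer(nAGQ),
      ranefProvince = setNames(uHat, levels(factor(df$province))),
      ranefOLRE = eHat, fitted = n * pHat, data = df,
      optimDetails = list(pearson = pearson, nVarComp = 1L + as.integer(olre),
                          message = opt$message %||% ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.olreModes <- function(y, n, a, sigmaE) {
  e <- rep(0, length(y))
  invVar <- 1 / sigmaE^2
  for (it in 1:40) {
    p <- plogis(a + e)
    step <- (y - n * p - e * invVar) / (-(n * p * (1 - p) + invVar))
    e <- e - pmin(pmax(step, -4), 4)
    if (max(abs(step)) < 1e-10) break
  }
  e
}

#' Fit the Poisson / negative-binomial mixed model for sighting recency
#'
#' County-level count response (by default the years since the most recent
#' reported sighting) with the selection-method fixed effect and a province
#' random intercept, fitted by adaptive Gauss-Hermite marginal maximum
#' likelihood. The negative binomial uses the quadratic (NB2)
#' parameterization, variance = mu + mu^2/theta, matching the variance
#' structure of the usual GLMM software families; counties with a missing
#' response are excluded.
#'
#' @param counties county summary data.frame (needs the response column,
#'   \code{selection_method}, \code{province})
#' @param response name of the count response column
#' @param family "poisson" or "negbinomial"
#' @param methodEffect include the selection-method fixed effect
#' @param thetaFixed optionally fix the NB size parameter instead of
#'   estimating it (it then does not count as a free parameter)
#' @param nAGQ quadrature nodes (default 15)
#' @param nStarts variance starting points (default 3)
#' @return a \linkS4class{ModelFit}
#' @export
fitCountGLMM <- function(counties, response = "min_years_ago",
                         family = c("poisson", "negbinomial"),
                         methodEffect = TRUE, thetaFixed = NULL,
                         nAGQ = 15L, nStarts = 3L) {
  family <- match.arg(family)
  df <- .modelFrame(counties, response)
  y <- df$y; x <- df$method
  if (any(y < 0) || any(y != round(y)))
    stop("count response must contain nonnegative integers")
  provIdx <- as.integer(factor(df$province))
  nProv <- max(provIdx)
  rule <- .ghRule(nAGQ)

  nFix <- if (methodEffect) 2L else 1L
  init <- c(log(mean(y) + 0.5), if (methodEffect) 0)
  estTheta <- family == "negbinomial" && is.null(thetaFixed)
  mEnv <- new.env(parent = emptyenv()); mEnv$u <- NULL

  negll <- function(par) {
    beta0 <- par[1]; beta1 <- if (methodEffect) par[2] else 0
    sigmaP <- exp(par[nFix + 1])
    theta <- if (family == "negbinomial") {
      if (estTheta) exp(par[nFix + 2]) else thetaFixed
    } else NA
    eta <- beta0 + beta1 * x
    cond <- function(A) {
      mu <- exp(pmin(pmax(A, -30), 30))
      if (family == "poisson")
        matrix(dpois(y, mu, log = TRUE), length(y))
      else
        matrix(dnbinom(y, size = theta, mu = mu, log = TRUE), length(y))
    }
    r <- tryCatch(.agqMarginal(eta, provIdx, nProv, sigmaP, cond, rule,
                               mEnv$u),
                  error = function(e) NULL)
    if (is.null(r) || !is.finite(r$logLik)) return(1e10)
    mEnv$u <- r$modes
    -r$logLik
  }

  opt <- .optimizeMarginal(negll, init, nSigma = 1L,
                           nExtra = as.integer(estTheta),
                           extraInit = if (estTheta) log(1) else numeric(),
                           nStarts = nStarts)
  par <- opt$par
  beta <- setNames(par[seq_len(nFix)], .coefNames(methodEffect))
  sigmaP <- exp(par[nFix + 1])
  theta <- if (family == "negbinomial") {
    if (estTheta) exp(par[nFix + 2]) else thetaFixed
  } else NA_real_

  eta <- beta[1] + (if (methodEffect) beta[2] else 0) * x
  cond <- function(A) {
    mu <- exp(pmin(pmax(A, -30), 30))
    if (family == "poisson") matrix(dpois(y, mu, log = TRUE), length(y))
    else matrix(dnbinom(y, size = theta, mu = mu, log = TRUE), length(y))
  }
  fin <- .agqMarginal(eta, provIdx, nProv, sigmaP, cond, rule, mEnv$u)
  uHat <- fin$modes
  muHat <- exp(eta + uHat[provIdx])
  vfun <- if (family == "poisson") muHat else muHat + muHat^2 / theta
  pearson <- (y - muHat) / sqrt(pmax(vfun, 1e-12))

  new("ModelFit",
      family = if (family == "poisson") "poisson" else "negbinomial",
      coefficients = beta,
      sigmaProvince = if (sigmaP < .SIGMA_REPORT_ZERO) 0 else sigmaP,
      sigmaOLRE = NA_real_, dispersion = theta, tweediePower = NA_real_,
      logLik = -opt$objective,
      nParameters = nFix + 1L + as.integer(estTheta),
      converged = is.finite(opt$objective) && opt$convergence == 0L,
      quadraturePoints = as.integer(nAGQ),
      ranefProvince = setNames(uHat, levels(factor(df$province))),
      ranefOLRE = numeric(0), fitted = muHat, data = df,
      optimDetails = list(pearson = pearson, nVarComp = 1L,
                          message = opt$message %||% ""))
}

#' Overdispersion ratio of a fitted model
#'
#' Sum of squared Pearson residuals (conditional on the estimated random
#' effects) divided by the residual degrees of freedom
#' (n - fixed effects - variance components). Values near 1 indicate the
#' assumed variance function holds; the analysis pipeline refits the
#' binomial model with an OLRE when this ratio is large.
#'
#' @param fit a \linkS4class{ModelFit}, or a numeric vector of Pearson
#'   residuals
#' @param df residual degrees of freedom (numeric-residual method only)
#' @return the dispersion ratio
#' @export
setGeneric("overdispersionRatio",
           function(fit, df) standardGeneric("overdispersionRatio"))

#' @rdname overdispersionRatio
#' @export
setMethod("overdispersionRatio", signature(fit = "ModelFit", df = "missing"),
  function(fit) {
    r <- fit@optimDetails$pearson
    rdf <- nrow(fit@data) - length(fit@coefficients) -
      fit@optimDetails$nVarComp
    if (rdf <= 0) stop("residual degrees of freedom must be positive")
    sum(r^2) / rdf
  })

#' @rdname overdispersionRatio
#' @export
setMethod("overdispersionRatio", signature(fit = "numeric", df = "numeric"),
  function(fit, df) {
    if (df <= 0) stop("residual degrees of freedom must be positive")
    sum(fit^2) / df
  })

#' Likelihood-ratio test of nested fits
#'
#' chi2 = max(0, 2 (llAlt - llNull)) on df = difference in parameter
#' counts, with the naive chi-squared reference the applied literature
#' uses. For a single variance component tested on its boundary the 50:50
#' mixture p-value is also reported (\code{pBoundary}).
#'
#' @param fitNull,fitAlt nested \linkS4class{ModelFit}s (null within alt)
#' @return list with chi2, df, p and pBoundary
#' @export
lrTest <- function(fitNull, fitAlt) {
  df <- fitAlt@nParameters - fitNull@nParameters
  if (df <= 0) stop("models are not nested (df <= 0)")
  chi2 <- 2 * (fitAlt@logLik - fitNull@logLik)
  if (chi2 < 0) {
    if (chi2 < -1e-6)
      warning(sprintf("alternative log-likelihood below null by %.3g; clamping chi2 to 0",
                      -chi2 / 2))
    chi2 <- 0
  }
  p <- pchisq(chi2, df, lower.tail = FALSE)
  pB <- if (chi2 == 0) 1 else 0.5 * pchisq(chi2, df, lower.tail = FALSE) +
    0.5 * (if (df > 1) pchisq(chi2, df - 1, lower.tail = FALSE) else 0)
  list(chi2 = chi2, df = df, p = p, pBoundary = min(pB, 1))
}

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("%s mixed model (AGQ, %d nodes)%s\n", object@family,
              object@quadraturePoints,
              if (!object@converged) " [NOT CONVERGED]" else ""))
  cat("  fixed effects (link scale):\n")
  for (nm in names(object@coefficients))
    cat(sprintf("    %-12s %8.4f\n", nm, object@coefficients[nm]))
  cat(sprintf("  sigma(province) = %.4f", object@sigmaProvince))
  if (is.finite(object@sigmaOLRE))
    cat(sprintf(", sigma(OLRE) = %.4f", object@sigmaOLRE))
  cat("\n")
  if (is.finite(object@dispersion))
    cat(sprintf("  dispersion = %.4f\n", object@dispersion))
  if (is.finite(object@tweediePower))
    cat(sprintf("  Tweedie power p = %.3f\n", object@tweediePower))
  cat(sprintf("  logLik = %.4f (%d parameters, n = %d)\n", object@logLik,
              object@nParameters, nrow(object@data)))
  invisible(object)
})
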