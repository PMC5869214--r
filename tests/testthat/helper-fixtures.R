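# shared fixtures, all generated in code

smallLandscapeConfig <- function(seed = 1L, ...) {
  landscapeConfig(gridRows = 30L, gridCols = 30L, nCounties = 8L,
                  nProvinces = 3L, autocorrelationLength = 5L,
                  seed = seed, ...)
}

# county-level binomial data with known random-effect structure,
# independent of the interview generator
makeBinomialCounties <- function(nProv, nPerProv, n = 30L, beta0 = 0,
                                 beta1 = 0.5, sigmaP = 0.5, sigmaE = 0,
                                 seed = 1L) {
  set.seed(seed)
  nC <- nProv * nPerProv
  prov <- rep(paste0("P", seq_len(nProv)), each = nPerProv)
  x <- rep_len(c(0L, 1L), nC)
  u <- rnorm(nProv, 0, sigmaP)
  e <- rnorm(nC, 0, sigmaE)
  p <- plogis(beta0 + beta1 * x + u[as.integer(factor(prov))] + e)
  data.frame(county_id = seq_len(nC), province = prov,
             selection_method = x, n_respondents = n,
             n_reported = rbinom(nC, n, p))
}

makeCountCounties <- function(nProv, nPerProv, beta0 = 1.5, beta1 = 0.3,
                              sigmaP = 0.4, family = "poisson", theta = 2,
                              seed = 1L, response = "min_years_ago") {
  set.seed(seed)
  nC <- nProv * nPerProv
  prov <- rep(paste0("P", seq_len(nProv)), each = nPerProv)
  x <- rep_len(c(0L, 1L), nC)
  u <- rnorm(nProv, 0, sigmaP)
  mu <- exp(beta0 + beta1 * x + u[as.integer(factor(prov))])
  y <- if (family == "poisson") rpois(nC, mu)
       else rnbinom(nC, size = theta, mu = mu)
  out <- data.frame(county_id = seq_len(nC), province = prov,
                    selection_method = x)
  out[[response]] <- y
  out
}

# compound Poisson-gamma simulator: the brute-force counterpart of the
# Tweedie series density
rtweedie <- function(n, mu, phi, p) {
  lam <- mu^(2 - p) / (phi * (2 - p))
  alpha <- (2 - p) / (p - 1)
  gam <- phi * (p - 1) * mu^(p - 1)
  N <- rpois(n, lam)
  y <- numeric(n)
  pos <- N > 0
  y[pos] <- rgamma(sum(pos), shape = N[pos] * alpha, scale = gam)
  y
}

makeTweedieCounties <- function(nProv = 10L, nPerProv = 8L, beta0 = 1.5,
                                beta1 = 0.3, sigmaP = 0.4, phi = 2,
                                p = 1.6, seed = 1L) {
  set.seed(seed)
  nC <- nProv * nPerProv
  prov <- rep(paste0("P", seq_len(nProv)), each = nPerProv)
  x <- rep_len(c(0L, 1L), nC)
  u <- rnorm(nProv, 0, sigmaP)
  mu <- exp(beta0 + beta1 * x + u[as.integer(factor(prov))])
  data.frame(county_id = seq_len(nC), province = prov,
             selection_method = x, mean_years_ago = rtweedie(nC, mu, phi, p))
}

# per-cell loop oracle for zonal statistics
bruteForceZonal <- function(suitability, zones) {
  s <- gridValues(suitability)
  z <- gridValues(zones)
  ids <- sort(unique(z[!is.na(z)]))
  do.call(rbind, lapply(ids, function(id) {
    nc <- 0L; ns <- 0L
    for (i in seq_len(nrow(z))) for (j in seq_len(ncol(z))) {
      if (is.na(z[i, j]) || z[i, j] != id) next
      if (is.na(s[i, j])) next
      nc <- nc + 1L
      if (s[i, j] == 1) ns <- ns + 1L
    }
    data.frame(zone_id = as.integer(id), n_cells = nc, n_suitable = ns,
               percent_suitable = if (nc > 0) 100 * ns / nc else NA_real_)
  }))
}

smallSurveyDesign <- function(nCounties = 20L, nProv = 4L) {
  # first half one arm, second half the other, provinces cyclic: every
  # province contains both arms (arm and province must not be confounded)
  data.frame(county_id = seq_len(nCounties),
             province = paste0("P", rep_len(seq_len(nProv), nCounties)),
             selection_method = rep(c(1L, 0L),
                                    c(ceiling(nCounties / 2),
                                      floor(nCounties / 2))))
}
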