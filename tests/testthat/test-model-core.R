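test_that("linear predictor assembles intercept, coefficients and offset", {
  panel <- tinyPanel(S = 3, Y = 4, predictors = c("x1", "x2"), seed = 5)
  geom <- strataGeometry(panel)
  pn <- predictorNames(panel)
  zeroW <- matrix(0, 3, 2)
  ## constant case: mu0 = 2, areas forced to exp(3) via a rebuilt panel
  ponds <- pondCounts(panel)
  g3 <- StrataGeometry(strataIds(geom), centroids(geom),
                       areas = rep(exp(3), 3))
  p3 <- PondPanel(ponds, list(x1 = matrix(0, 3, 4), x2 = matrix(0, 3, 4)),
                  g3)
  par0 <- SVCParameters(mu0 = 2, mu_beta = setNames(c(0, 0), pn),
                        w0 = rep(0, 3), W = zeroW, sigma_beta0 = 1,
                        sigma_beta = c(1, 1), tau = rep(0.5, 3),
                        rho = diag(2), phi0 = 1e-3, phiB = 1e-3)
  expect_true(all(linearPredictor(par0, p3) == 5))
  ## single active predictor: X = 1.5 and total coefficient 2 gives 3
  g1 <- StrataGeometry(strataIds(geom), centroids(geom), areas = rep(1, 3))
  p1 <- PondPanel(ponds, list(x1 = matrix(1.5, 3, 4), x2 = matrix(0, 3, 4)),
                  g1)
  par1 <- SVCParameters(mu0 = 0, mu_beta = setNames(c(1.2, 0), pn),
                        w0 = rep(0, 3),
                        W = cbind(rep(0.8, 3), rep(0, 3)),
                        sigma_beta0 = 1, sigma_beta = c(1, 1),
                        tau = rep(0.5, 3), rho = diag(2),
                        phi0 = 1e-3, phiB = 1e-3)
  expect_true(all(abs(linearPredictor(par1, p1) - 3) < 1e-12))
  ## doubling every area adds log(2) everywhere
  g2 <- StrataGeometry(strataIds(geom), centroids(geom),
                       areas = 2 * strataAreas(geom))
  p2a <- PondPanel(ponds, list(x1 = matrix(0, 3, 4), x2 = matrix(0, 3, 4)),
                   geom)
  p2b <- PondPanel(ponds, list(x1 = matrix(0, 3, 4), x2 = matrix(0, 3, 4)),
                   g2)
  expect_equal(linearPredictor(par0, p2b),
               linearPredictor(par0, p2a) + log(2))
})

test_that("lognormal observation log-likelihood matches closed forms", {
  panel <- tinyPanel(S = 3, Y = 4, predictors = c("x1", "x2"), seed = 6)
  ponds <- pondCounts(panel)
  mu <- log(ponds)  # at the log-scale mode everywhere
  tau <- c(0.3, 0.5, 0.7)
  ll <- observationLoglik(panel, mu, tau)
  expect_equal(ll, sum(dlnorm(ponds, log(ponds), rep(tau, 4), log = TRUE)))
  ## single-cell closed form, includes the 1/x Jacobian
  expect_equal(dlnorm(100, log(100), 0.5, log = TRUE),
               -log(0.5) - 0.5 * log(2 * pi) - log(100))
  expect_equal(dlnorm(100, log(100), 0.5, log = TRUE), -4.8310, tolerance = 1e-4)
  ## additivity over cells
  one <- tinyPanel(S = 3, Y = 4, predictors = c("x1", "x2"), seed = 6)
  perCell <- dlnorm(ponds, mu, rep(tau, 4), log = TRUE)
  expect_equal(ll, sum(perCell))
  expect_error(observationLoglik(panel, mu, c(-1, 0.5, 0.7)), "positive")
})

test_that("phi prior bounds invert the kernel at the distance extremes", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 100
  D[1, 3] <- D[3, 1] <- 1000
  D[2, 3] <- D[3, 2] <- 500
  b <- phiPriorBounds(D)
  expect_equal(b@lower, sqrt(-log(0.90)) / 1000, tolerance = 1e-12)
  expect_equal(b@upper, sqrt(-log(0.01)) / 100, tolerance = 1e-12)
  expect_equal(b@lower, 3.246e-4, tolerance = 1e-3)
  expect_equal(b@upper, 2.146e-2, tolerance = 1e-3)
  ## round trips: the kernel attains the stated correlations exactly
  expect_equal(gaussianCorrelation(b@lower, 1000), 0.90, tolerance = 1e-12)
  expect_equal(gaussianCorrelation(b@upper, 100), 0.01, tolerance = 1e-12)
  D0 <- matrix(0, 3, 3)
  expect_error(phiPriorBounds(D0), "zero distance")
})

test_that("log-prior combines the documented hyperpriors", {
  ## Gamma(1.2, 0.2) moments used as a prior-predictive sanity check
  expect_equal(1.2 / 0.2, 6)
  expect_equal(sqrt(1.2) / 0.2, 5.477, tolerance = 1e-3)
  panel <- tinyPanel(S = 3, Y = 5, predictors = c("x1", "x2"), seed = 7)
  geom <- strataGeometry(panel)
  params <- tinyParams(panel, seed = 7)
  bounds <- phiPriorBounds(distanceMatrix(geom))
  lp <- logPrior(params, bounds)
  ## each zero-valued mean effect contributes the normal mode density
  p0 <- params; p0@mu_beta[] <- 0
  expect_equal(logPrior(p0, bounds) - lp,
               2 * (-log(10) - 0.5 * log(2 * pi)) -
                 sum(dnorm(params@mu_beta, 0, 10, log = TRUE)))
  ## phi outside the uniform support is flagged -Inf
  pbad <- params; pbad@phi0 <- bounds@upper * 1.01
  lpbad <- logPrior(pbad, bounds)
  expect_identical(as.numeric(lpbad), -Inf)
  expect_match(attr(lpbad, "reason"), "bounds")
  ## geometry adds the two random-field terms
  withG <- logPrior(params, bounds, geom)
  D <- distanceMatrix(geom)
  expect_equal(withG - lp,
               matrixNormalLogpdf(params@W,
                                  gaussianCorrelation(params@phiB, D),
                                  buildT(params@sigma_beta, params@rho)) +
                 mvnLogpdfOracle(params@w0,
                                 params@sigma_beta0^2 *
                                   gaussianCorrelation(params@phi0, D)),
               tolerance = 1e-8)
})

test_that("log-posterior is the sum of prior, field and observation terms", {
  panel <- tinyPanel(S = 4, Y = 6, predictors = c("x1", "x2", "x3"), seed = 8)
  geom <- strataGeometry(panel)
  params <- tinyParams(panel, seed = 8)
  bounds <- phiPriorBounds(distanceMatrix(geom))
  lp <- logPosterior(params, panel)
  expect_true(is.finite(lp))
  expect_equal(lp, logPrior(params, bounds, geom) +
                 observationLoglik(panel, linearPredictor(params, panel),
                                   params@tau))
  ## moving tau far from the residual scale of a model-generated panel
  ## lowers the posterior in both directions
  sim <- simulateStudy(n_strata = 4, n_years = 12, seed = 77,
                       truth = tameTruth())
  ptrue <- sim$truth
  lp0 <- logPosterior(ptrue, sim$panel)
  pbig <- ptrue; pbig@tau <- rep(50, 4)
  expect_lt(logPosterior(pbig, sim$panel), lp0)
  ptiny <- ptrue; ptiny@tau <- ptrue@tau / 100
  expect_lt(logPosterior(ptiny, sim$panel), lp0)
})

test_that("log-posterior matches a monolithic vec-and-Kronecker oracle", {
  ## 3 strata x 2 predictors, the full joint density written as one MVN
  ## over all stacked Gaussian effects plus scalar prior/likelihood sums
  panel <- tinyPanel(S = 3, Y = 6, predictors = c("a", "b"), seed = 9)
  geom <- strataGeometry(panel)
  D <- distanceMatrix(geom)
  bounds <- phiPriorBounds(D)
  params <- tinyParams(panel, seed = 10)
  lp <- logPosterior(params, panel)

  K0 <- exp(-params@phi0^2 * D^2)
  KB <- exp(-params@phiB^2 * D^2)
  Tm <- diag(params@sigma_beta) %*% params@rho %*% diag(params@sigma_beta)
  big <- matrix(0, 3 + 6, 3 + 6)
  big[1:3, 1:3] <- params@sigma_beta0^2 * K0
  big[4:9, 4:9] <- kronecker(KB, Tm)  # row-major vec of W
  effects <- c(params@w0, as.vector(t(params@W)))
  oracle <- mvnLogpdfOracle(effects, big)
  oracle <- oracle + sum(dnorm(c(params@mu0, params@mu_beta), 0, 10,
                               log = TRUE)) +
    sum(dgamma(c(params@sigma_beta0, params@sigma_beta, params@tau),
               1.2, rate = 0.2, log = TRUE)) +
    lkjLogpdf(params@rho) - 2 * log(bounds@upper - bounds@lower)
  X <- designArray(panel)
  ponds <- pondCounts(panel)
  for (s in 1:3) for (t in 1:6) {
    m <- params@mu0 + params@w0[s] + log(strataAreas(geom)[s]) +
      sum((params@mu_beta + params@W[s, ]) * X[s, t, -1])
    oracle <- oracle + dlnorm(ponds[s, t], m, params@tau[s], log = TRUE)
  }
  expect_equal(lp, oracle, tolerance = 1e-8)
})
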