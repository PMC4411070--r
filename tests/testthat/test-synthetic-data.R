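test_that("simulated climate is positive, deterministic and spatially
           correlated at the generating kernel", {
  geom <- makeGeometry(8, extent_km = 1200, seed = 4)
  c1 <- simulateClimate(geom, n_years = 200, phi_clim = 0.002, seed = 8)
  c2 <- simulateClimate(geom, n_years = 200, phi_clim = 0.002, seed = 8)
  expect_identical(c1@precip, c2@precip)
  expect_true(all(c1@precip > 0))
  ## sample correlation of a season's log-precip field across years vs the
  ## analytic kernel (Monte-Carlo check, +- 0.1)
  lp <- log(c1@precip[, , 3])
  emp <- cor(t(lp))
  K <- gaussianCorrelation(0.002, distanceMatrix(geom))
  off <- upper.tri(K)
  expect_lt(max(abs(emp[off] - K[off])), 0.25)
  expect_lt(mean(abs(emp[off] - K[off])), 0.1)
  ## large phi kills inter-stratum correlation
  cfar <- simulateClimate(geom, n_years = 200, phi_clim = 1, seed = 8)
  empfar <- cor(t(log(cfar@precip[, , 3])))
  expect_lt(max(abs(empfar[off])), 0.35)
})

test_that("drawParameters samples the generative hierarchy", {
  geom <- makeGeometry(4, extent_km = 1200, seed = 5)
  cfg <- truthConfig(mu_beta = c(lag = 0.2, time = 0, precip_winter = 0.3),
                     sigma_beta = c(lag = 0.3, time = 0.1,
                                    precip_winter = 0.2),
                     sigma_beta0 = 1, rho = randomCorr(3))
  p1 <- drawParameters(geom, cfg, seed = 6)
  p2 <- drawParameters(geom, cfg, seed = 6)
  expect_identical(p1@W, p2@W)
  ## degenerate scales give identically zero fields
  cfg0 <- cfg; cfg0$sigma_beta <- rep(0, 3); cfg0$sigma_beta0 <- 0
  p0 <- drawParameters(geom, cfg0, seed = 6)
  expect_true(all(p0@W == 0))
  expect_true(all(p0@w0 == 0))
  ## empirical covariance of many drawn fields recovers K (x) T
  nrep <- 5000
  draws <- matrix(NA_real_, nrep, 4 * 3)
  for (i in seq_len(nrep))
    draws[i, ] <- as.vector(drawParameters(geom, cfg, seed = 1000 + i)@W)
  emp <- cov(draws)
  K <- gaussianCorrelation(cfg$phiB, distanceMatrix(geom))
  Tm <- buildT(cfg$sigma_beta, cfg$rho)
  target <- kronecker(Tm, K)  # column-major vec
  relerr <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(relerr, 0.10)
  ## truth phi outside the geometry's prior bounds is rejected
  cfgbad <- cfg; cfgbad$phiB <- 1
  expect_error(drawParameters(geom, cfgbad, seed = 1), "bounds")
})

test_that("pond simulation is a lognormal autoregression on the design", {
  geom <- makeGeometry(4, extent_km = 1200, seed = 7)
  clim <- simulateClimate(geom, n_years = 10, seed = 7)
  ## deterministic fixed point: no noise, no coefficients, zero offset
  g1 <- StrataGeometry(strataIds(geom), centroids(geom), areas = rep(1, 4))
  cfg <- truthConfig(mu0 = 2, sigma_beta0 = 0,
                     mu_beta = setNames(rep(0, 10), names(truthConfig()$mu_beta)),
                     sigma_beta = setNames(rep(0, 10), names(truthConfig()$mu_beta)),
                     tau_range = c(1e-9, 1.0001e-9))
  par <- drawParameters(g1, cfg, seed = 3)
  panel <- simulatePonds(par, clim, g1, seed = 3)
  expect_equal(unname(pondCounts(panel)[, -1]),
               matrix(exp(2), 4, 9), tolerance = 1e-6)
  ## all counts positive under the defaulted realistic truth
  par2 <- drawParameters(geom, truthConfig(sigma_beta0 = 2), seed = 4)
  panel2 <- simulatePonds(par2, clim, geom, seed = 4)
  expect_true(all(pondCounts(panel2) > 0))
  ## identical seeds reproduce the panel bit-exactly
  panel3 <- simulatePonds(par2, clim, geom, seed = 4)
  expect_identical(pondCounts(panel2), pondCounts(panel3))
  ## an explosive lag coefficient warns
  cfgx <- truthConfig(mu_beta = c(lag = 1.2, time = 0,
                                  precip_winter = 0),
                      sigma_beta = c(lag = 0, time = 0, precip_winter = 0),
                      sigma_beta0 = 0)
  parx <- drawParameters(geom, cfgx, seed = 5)
  expect_warning(simulatePonds(parx, clim, geom, seed = 5),
                 "non-stationary")
})

test_that("simulated residual dispersion recovers tau over a long horizon", {
  geom <- makeGeometry(4, extent_km = 1200, seed = 9)
  clim <- simulateClimate(geom, n_years = 500, seed = 9)
  par <- drawParameters(geom, truthConfig(sigma_beta0 = 1.5), seed = 9)
  panel <- simulatePonds(par, clim, geom, seed = 9)
  mu <- linearPredictor(par, panel)
  resid <- log(pondCounts(panel))[, -1] - mu[, -1]
  sdhat <- apply(resid, 1, sd)
  expect_lt(max(abs(sdhat / par@tau - 1)), 0.10)
  expect_lt(mean(abs(sdhat / par@tau - 1)), 0.05)
})

test_that("stationary lag dynamics keep the log series bounded", {
  geom <- makeGeometry(4, extent_km = 1200, seed = 10)
  clim <- simulateClimate(geom, n_years = 400, seed = 10)
  par <- drawParameters(geom, truthConfig(sigma_beta0 = 1), seed = 10)
  expect_true(all(abs(par@mu_beta["lag"] + par@W[, 1]) < 1))
  panel <- simulatePonds(par, clim, geom, seed = 10)
  y <- log(pondCounts(panel))
  v1 <- apply(y[, 2:200], 1, var)
  v2 <- apply(y[, 201:400], 1, var)
  ## variance in the second half does not blow up relative to the first
  expect_lt(max(v2 / v1), 3)
})

test_that("simulateStudy is reproducible end to end from one seed", {
  s1 <- simulateStudy(n_strata = 6, n_years = 8, seed = 11,
                      truth = tameTruth())
  s2 <- simulateStudy(n_strata = 6, n_years = 8, seed = 11,
                      truth = tameTruth())
  expect_identical(pondCounts(s1$panel), pondCounts(s2$panel))
  expect_identical(s1$truth@W, s2$truth@W)
})
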