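test_that("split-Rhat behaves at its analytic anchors", {
  ## i.i.d. half-chains: values hug 1
  set.seed(31)
  reps <- replicate(200, splitRhat(matrix(rnorm(4 * 100), 4, 100)))
  expect_gt(mean(reps >= 0.99 & reps <= 1.02), 0.95)
  ## chains at different constants: dominated by between-chain variance
  x <- rbind(rep(1, 50), rep(2, 50))
  expect_identical(splitRhat(x), Inf)
  ## identical constant chains: flagged undefined, not silently 1
  expect_true(is.na(splitRhat(rbind(rep(3, 50), rep(3, 50)))))
  expect_error(splitRhat(matrix(1, 2, 3)), "at least 4")
  ## a clearly drifting chain is caught
  drift <- rbind(seq(0, 1, length.out = 100), seq(1, 0, length.out = 100))
  expect_gt(splitRhat(drift), 1.5)
})

test_that("convergence gate applies the pass/warn/fail thresholds", {
  expect_identical(convergenceGate(c(1.01, 1.04))$status, "pass")
  expect_identical(convergenceGate(c(1.01, 1.08))$status, "warn")
  expect_identical(convergenceGate(c(1.2))$status, "fail")
  expect_identical(convergenceGate(c(1.01, NA))$status, "pass")
  expect_identical(convergenceGate(Inf)$status, "fail")
})

test_that("posterior summaries use interpolated order statistics and flag
           intervals excluding zero", {
  set.seed(32)
  a <- array(NA_real_, c(1, 100, 3),
             dimnames = list(NULL, NULL, c("p1", "p2", "p3")))
  a[1, , 1] <- sample(1:100)
  a[1, , 2] <- c(rnorm(50, 5, 0.1), rnorm(50, -5, 0.1))  # symmetric-ish
  a[1, , 3] <- rlnorm(100)
  pd <- new("PosteriorDraws", draws = a,
            parameter_names = c("p1", "p2", "p3"), seed = 1L, warmup = 0L,
            kept = 100L, thin = 1L, diagnostics = list())
  s <- posteriorSummary(pd)
  expect_equal(s$median[1], 50.5)
  expect_equal(s$ci_lo[1], 3.475)    # type-7 quantile of 1..100 at 0.025
  expect_equal(s$ci_hi[1], 97.525)
  expect_false(s$significant[2])
  expect_true(s$significant[3])
  expect_identical(attr(s, "quantile_type"), 7L)
})

test_that("with the spatial fields switched off the sampler reproduces the
           conjugate Bayesian regression", {
  panel <- tinyPanel(S = 4, Y = 10, predictors = c("a", "b"), seed = 33)
  prep <- pondSVC:::.prepPanel(panel)
  tau0 <- rep(0.3, 4)
  ctrl <- mcmcControl(fixed = list(tau = tau0, sigma_beta0 = 0,
                                   sigma_beta = c(0, 0), rho = diag(2),
                                   phi0 = 1e-3, phiB = 1e-3))
  fit <- runMCMC(panel, chains = 2, warmup = 10, kept = 400, thin = 1,
                 seed = 34, control = ctrl)
  ## conjugate oracle: ridge regression with prior sd 10
  Fm <- prep$F
  Q <- diag(1 / 100, 3) + crossprod(Fm) / 0.3^2
  m <- drop(solve(Q, crossprod(Fm, prep$r) / 0.3^2))
  V <- solve(Q)
  s <- posteriorSummary(fit)
  est <- s$median[match(c("mu0", "mu_beta[a]", "mu_beta[b]"), s$parameter)]
  expect_lt(max(abs(est - m) / sqrt(diag(V))), 2 / sqrt(400) * 6)
  ## posterior sd close to the oracle sd
  dm <- drawsMatrix(fit)
  sds <- apply(dm[, c("mu0", "mu_beta[a]", "mu_beta[b]")], 2, sd)
  expect_lt(max(abs(sds / sqrt(diag(V)) - 1)), 0.2)
})

test_that("identical seeds give identical draws; different seeds differ", {
  sim <- simulateStudy(n_strata = 5, n_years = 8, seed = 35,
                       truth = tameTruth())
  f1 <- runMCMC(sim$panel, chains = 1, warmup = 20, kept = 20, seed = 36)
  f2 <- runMCMC(sim$panel, chains = 1, warmup = 20, kept = 20, seed = 36)
  f3 <- runMCMC(sim$panel, chains = 1, warmup = 20, kept = 20, seed = 37)
  expect_identical(f1@draws, f2@draws)
  expect_false(identical(f1@draws, f3@draws))
  expect_true(all(is.finite(f1@draws)))
})

test_that("posterior draws of phi never leave the uniform prior support", {
  sim <- simulateStudy(n_strata = 5, n_years = 10, seed = 38,
                       truth = tameTruth())
  fit <- runMCMC(sim$panel, chains = 1, warmup = 50, kept = 100, seed = 39)
  b <- phiPriorBounds(distanceMatrix(sim$geometry))
  dm <- drawsMatrix(fit)
  expect_true(all(dm[, "phi0"] >= b@lower & dm[, "phi0"] <= b@upper))
  expect_true(all(dm[, "phiB"] >= b@lower & dm[, "phiB"] <= b@upper))
})
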