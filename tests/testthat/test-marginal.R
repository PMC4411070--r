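## The collapsed-sampler machinery: the marginal likelihood with the
## Gaussian layers integrated out, and the exact conditional of that layer.

makeHyper <- function(prep, seed = 1) {
  set.seed(seed)
  list(sigma_beta0 = runif(1, 0.5, 1.5),
       sigma_beta = runif(prep$P, 0.05, 0.4),
       tau = runif(prep$S, 0.1, 0.4),
       rho = randomCorr(prep$P),
       phi0 = 1e-3, phiB = 1.5e-3)
}

test_that("marginal likelihood equals a dense brute-force construction", {
  panel <- tinyPanel(S = 4, Y = 7, predictors = c("a", "b", "c"), seed = 12)
  geom <- strataGeometry(panel)
  prep <- pondSVC:::.prepPanel(panel)
  for (sd in 1:3) {
    hyper <- makeHyper(prep, seed = sd)
    ## dense oracle: y = A u + eps with u ~ N(0, Sigma_u) spelled out
    S <- prep$S; P <- prep$P; n <- prep$n
    Z0 <- matrix(0, n, S); ZW <- matrix(0, n, S * P)
    for (i in seq_len(n)) {
      s <- prep$si[i]
      Z0[i, s] <- 1
      for (p in seq_len(P)) ZW[i, (p - 1) * S + s] <- prep$Xn[i, p]
    }
    A <- cbind(prep$F, Z0, ZW)
    D <- distanceMatrix(geom)
    SigU <- matrix(0, ncol(A), ncol(A))
    SigU[1:(1 + P), 1:(1 + P)] <- diag(100, 1 + P)
    SigU[(1 + P) + 1:S, (1 + P) + 1:S] <-
      hyper$sigma_beta0^2 * exp(-hyper$phi0^2 * D^2)
    iW <- (1 + P + S) + 1:(S * P)
    SigU[iW, iW] <- kronecker(tcrossprod(hyper$sigma_beta) * hyper$rho,
                              exp(-hyper$phiB^2 * D^2))
    Cfull <- A %*% SigU %*% t(A) + diag(hyper$tau[prep$si]^2)
    oracle <- mvnLogpdfOracle(prep$r, Cfull) + prep$jac
    expect_equal(pondSVC:::.marginalLoglik(hyper, prep), oracle,
                 tolerance = 1e-8)
    ## compiled and reference-R paths agree
    expect_equal(pondSVC:::.marginalLoglik(hyper, prep),
                 pondSVC:::.marginalLoglikR(hyper, prep), tolerance = 1e-6)
  }
})

test_that("marginal times conditional equals likelihood times field prior", {
  ## p(y | hyper) p(u | y, hyper) == p(y | u, tau) p(u | hyper) pointwise:
  ## the factorization at the heart of the collapsed sampler
  panel <- tinyPanel(S = 4, Y = 6, predictors = c("a", "b"), seed = 13)
  geom <- strataGeometry(panel)
  D <- distanceMatrix(geom)
  prep <- pondSVC:::.prepPanel(panel)
  hyper <- makeHyper(prep, seed = 5)
  cond <- pondSVC:::.conditionalEffects(hyper, prep)
  set.seed(99)
  u <- cond$mean + rnorm(length(cond$mean), 0, 0.3)
  qf <- sum((cond$cholQ %*% (u - cond$mean))^2)
  log_cond <- -0.5 * length(u) * log(2 * pi) +
    sum(log(diag(cond$cholQ))) - 0.5 * qf
  lhs <- pondSVC:::.marginalLoglik(hyper, prep) + log_cond

  eff <- pondSVC:::.expandEffects(u, cond$layout, prep)
  pn <- predictorNames(panel)
  params <- SVCParameters(mu0 = eff$mu0,
                          mu_beta = setNames(eff$mu_beta, pn),
                          w0 = eff$w0, W = eff$W,
                          sigma_beta0 = hyper$sigma_beta0,
                          sigma_beta = hyper$sigma_beta, tau = hyper$tau,
                          rho = hyper$rho, phi0 = hyper$phi0,
                          phiB = hyper$phiB)
  rhs <- observationLoglik(panel, linearPredictor(params, panel), hyper$tau) +
    mvnLogpdfOracle(c(eff$mu0, eff$mu_beta), diag(100, 3)) +
    mvnLogpdfOracle(eff$w0, hyper$sigma_beta0^2 * exp(-hyper$phi0^2 * D^2)) +
    matrixNormalLogpdf(eff$W, exp(-hyper$phiB^2 * D^2),
                       tcrossprod(hyper$sigma_beta) * hyper$rho)
  expect_equal(lhs, rhs, tolerance = 1e-7)
})

test_that("zero field scales drop the corresponding blocks", {
  panel <- tinyPanel(S = 4, Y = 6, predictors = c("a", "b"), seed = 14)
  prep <- pondSVC:::.prepPanel(panel)
  hyper <- makeHyper(prep, seed = 6)
  hyper$sigma_beta0 <- 0
  hyper$sigma_beta <- c(0, 0)
  ## marginal reduces to fixed effects plus noise
  Cfix <- 100 * prep$FFt + diag(hyper$tau[prep$si]^2)
  expect_equal(pondSVC:::.marginalLoglik(hyper, prep),
               mvnLogpdfOracle(prep$r, Cfix) + prep$jac, tolerance = 1e-8)
  set.seed(1)
  eff <- pondSVC:::.drawEffects(hyper, prep)
  expect_true(all(eff$w0 == 0))
  expect_true(all(eff$W == 0))
})

test_that("conditional mean matches the conjugate regression solution when
           the spatial fields are off", {
  panel <- tinyPanel(S = 4, Y = 8, predictors = c("a", "b"), seed = 15)
  prep <- pondSVC:::.prepPanel(panel)
  hyper <- list(sigma_beta0 = 0, sigma_beta = c(0, 0),
                tau = rep(0.3, 4), rho = diag(2), phi0 = 1e-3, phiB = 1e-3)
  cond <- pondSVC:::.conditionalEffects(hyper, prep)
  ## ridge solution with prior precision 1/100
  Fm <- prep$F
  Q <- diag(1 / 100, 3) + crossprod(Fm) / 0.3^2
  m <- solve(Q, crossprod(Fm, prep$r) / 0.3^2)
  expect_equal(cond$mean, unname(drop(m)), tolerance = 1e-8)
})
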