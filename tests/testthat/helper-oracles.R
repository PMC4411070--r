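## Independent oracles and small fixture builders, all generated in code.

## Multivariate normal log-density via solve()/determinant(), deliberately
## not sharing the package's Cholesky route.
mvnLogpdfOracle <- function(x, Sigma, mean = 0) {
  d <- x - mean
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (length(x) * log(2 * pi) + ld +
            drop(t(d) %*% solve(Sigma) %*% d))
}

## random positive-definite covariance with moderate conditioning
randomCov <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + diag(d)
}

## rejection-sampled uniform correlation matrix (small d only)
randomCorr <- function(d) {
  repeat {
    R <- diag(d)
    R[upper.tri(R)] <- runif(d * (d - 1) / 2, -1, 1)
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    if (!is.null(tryCatch(chol(R), error = function(e) NULL))) return(R)
  }
}

## small synthetic study with a tame intercept field (fast, well scaled)
tameTruth <- function(P = NULL) {
  truthConfig(sigma_beta0 = 1.2)
}

## tiny panel with arbitrary predictor names (no lag), for oracle tests
tinyPanel <- function(S = 3, Y = 6, predictors = c("x1", "x2"), seed = 1) {
  set.seed(seed)
  geom <- makeGeometry(S, extent_km = 800, seed = seed)
  preds <- lapply(predictors, function(p) matrix(rnorm(S * Y), S, Y))
  names(preds) <- predictors
  ponds <- matrix(rlnorm(S * Y, meanlog = 8, sdlog = 0.4), S, Y)
  colnames(ponds) <- as.character(2000 + seq_len(Y))
  PondPanel(ponds, preds, geom, years = 2000 + seq_len(Y))
}

## parameters matching a panel, drawn smoothly around zero
tinyParams <- function(panel, seed = 1, sigma_beta0 = 0.8, phi0 = 1e-3,
                       phiB = 1.5e-3) {
  set.seed(seed)
  pn <- predictorNames(panel)
  S <- nrow(panel); P <- length(pn)
  rho <- randomCorr(P)
  SVCParameters(mu0 = rnorm(1), mu_beta = setNames(rnorm(P, 0, 0.3), pn),
                w0 = rnorm(S, 0, 0.5), W = matrix(rnorm(S * P, 0, 0.2), S, P),
                sigma_beta0 = sigma_beta0,
                sigma_beta = runif(P, 0.1, 0.4),
                tau = runif(S, 0.2, 0.5), rho = rho,
                phi0 = phi0, phiB = phiB)
}
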