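## Collapsed (marginal) likelihood machinery.
##
## Every Gaussian layer of the model -- the global means (Normal prior), the
## intercept field w0 and the coefficient field W -- enters the log-scale
## likelihood linearly with Gaussian noise, so it can be integrated out in
## closed form.  The sampler explores only the hyperparameters
## (tau, sigma_beta0, sigma_beta, rho, phi0, phiB) under the marginal
## likelihood, and the Gaussian layer is then drawn exactly from its
## conditional for each kept iteration.  This targets the identical joint
## posterior as sampling all parameters at once.

## Unroll a panel into observation-level vectors (modeled cells only,
## year-major within stratum-fastest column-major order).
.prepPanel <- function(panel, geometry = strataGeometry(panel)) {
  yrs <- modeledYears(panel)
  ponds <- pondCounts(panel)[, yrs, drop = FALSE]
  S <- nrow(ponds); M <- ncol(ponds)
  pn <- predictorNames(panel)
  P <- length(pn)
  y <- as.vector(log(ponds))
  si <- rep.int(seq_len(S), M)
  Xn <- matrix(NA_real_, S * M, P, dimnames = list(NULL, pn))
  for (k in seq_len(P))
    Xn[, k] <- as.vector(SummarizedExperiment::assay(panel, pn[k])[, yrs, drop = FALSE])
  offs <- offsetLogArea(panel)[si]
  F <- cbind(intercept = 1, Xn)
  n <- S * M
  ## full observation-level design of the Gaussian layer
  ## columns: (1, Xn | Z0 | ZW_1..ZW_P), fixed across hyperparameters
  A <- matrix(0, n, 1L + P + S + S * P)
  A[, seq_len(1L + P)] <- F
  A[cbind(seq_len(n), 1L + P + si)] <- 1
  for (p in seq_len(P))
    A[cbind(seq_len(n), 1L + P + S + (p - 1L) * S + si)] <- Xn[, p]
  list(y = y, r = y - offs, si = si, Xn = Xn, F = F, FFt = tcrossprod(F),
       A = A, S = S, M = M, P = P, n = n, D = distanceMatrix(geometry),
       D2 = unname(distanceMatrix(geometry)^2), si0 = si - 1L,
       jac = -sum(y))
}

## hyper: list(sigma_beta0, sigma_beta, tau, rho, phi0, phiB)
.marginalCov <- function(hyper, prep, mu_sd = 10) {
  si <- prep$si
  C <- mu_sd^2 * prep$FFt
  if (hyper$sigma_beta0 > 0) {
    K0 <- exp(-hyper$phi0^2 * prep$D^2)
    C <- C + hyper$sigma_beta0^2 * K0[si, si]
  }
  if (any(hyper$sigma_beta > 0)) {
    KB <- exp(-hyper$phiB^2 * prep$D^2)
    Tm <- tcrossprod(hyper$sigma_beta) * hyper$rho
    C <- C + KB[si, si] * (prep$Xn %*% Tm %*% t(prep$Xn))
  }
  d <- diag(C) + hyper$tau[si]^2
  diag(C) <- d
  C
}

## Marginal log-likelihood of the pond counts given hyperparameters only
## (includes the lognormal 1/x Jacobian so it is a density for the counts).
## The dense-covariance evaluation lives in src/marginal.cpp; the pure-R
## .marginalCov path below is retained for the conditional draws and as an
## independent construction for tests.
.marginalLoglik <- function(hyper, prep, mu_sd = 10) {
  ll <- .marginalLoglikCpp(prep$r, prep$si0, unname(prep$Xn), prep$FFt,
                           prep$D2, hyper$sigma_beta0, hyper$sigma_beta,
                           hyper$tau, hyper$rho, hyper$phi0, hyper$phiB,
                           mu_sd^2)
  if (!is.finite(ll)) return(-Inf)
  ll + prep$jac
}

## Reference R implementation of the same quantity (slow path).
.marginalLoglikR <- function(hyper, prep, mu_sd = 10) {
  C <- .marginalCov(hyper, prep, mu_sd)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  z <- backsolve(R, prep$r, transpose = TRUE)
  -0.5 * (prep$n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z * z)) + prep$jac
}

## Which effect blocks are active (zero-scale fields are identically zero
## and are dropped from the conditional).
.effectLayout <- function(hyper, prep) {
  act0 <- hyper$sigma_beta0 > 0
  actW <- which(hyper$sigma_beta > 0)
  k_b <- 1L + prep$P
  list(act0 = act0, actW = actW,
       k = k_b + (if (act0) prep$S else 0L) + length(actW) * prep$S,
       k_b = k_b)
}

## Observation-level design of the active Gaussian layer:
## the cached full design restricted to the active columns.
.effectDesign <- function(hyper, prep) {
  lay <- .effectLayout(hyper, prep)
  cols <- seq_len(lay$k_b)
  if (lay$act0) cols <- c(cols, lay$k_b + seq_len(prep$S))
  for (p in lay$actW)
    cols <- c(cols, lay$k_b + prep$S + (p - 1L) * prep$S + seq_len(prep$S))
  list(A = prep$A[, cols, drop = FALSE], layout = lay)
}

## Conditional distribution of the stacked Gaussian layer
## u = (mu0, mu_beta, [w0], [vec W_active]) given data and hyperparameters,
## in precision form (numerically stable: no large-covariance subtraction):
##   Q = Sigma_u^-1 + A' D^-1 A,  mean = Q^-1 A' D^-1 r.
## Returns the mean and the upper Cholesky factor of Q.
.conditionalEffects <- function(hyper, prep, mu_sd = 10, ed = NULL) {
  if (is.null(ed)) ed <- .effectDesign(hyper, prep)
  lay <- ed$layout
  k <- ncol(ed$A)
  Qprior <- matrix(0, k, k)
  ib <- seq_len(lay$k_b)
  Qprior[cbind(ib, ib)] <- 1 / mu_sd^2
  at <- lay$k_b
  if (lay$act0) {
    K0 <- exp(-hyper$phi0^2 * prep$D^2)
    idx <- at + seq_len(prep$S)
    Qprior[idx, idx] <- chol2inv(.cholJitter(K0, "K0")) / hyper$sigma_beta0^2
    at <- at + prep$S
  }
  if (length(lay$actW)) {
    KB <- exp(-hyper$phiB^2 * prep$D^2)
    KBinv <- chol2inv(.cholJitter(KB, "KB"))
    s <- hyper$sigma_beta[lay$actW]
    Tm <- tcrossprod(s) * hyper$rho[lay$actW, lay$actW, drop = FALSE]
    Tinv <- chol2inv(.cholJitter(Tm, "T"))
    idx <- at + seq_len(length(lay$actW) * prep$S)
    Qprior[idx, idx] <- kronecker(Tinv, KBinv)
  }
  w <- 1 / hyper$tau[prep$si]
  Aw <- ed$A * w
  Q <- Qprior + crossprod(Aw)
  Q <- (Q + t(Q)) / 2
  cholQ <- .cholJitter(Q, "conditional effect precision")
  rhs <- drop(crossprod(Aw, prep$r * w))
  m <- backsolve(cholQ, backsolve(cholQ, rhs, transpose = TRUE))
  list(mean = m, cholQ = cholQ, layout = lay)
}

## One exact draw of the Gaussian layer, expanded to full
## (mu0, mu_beta, w0, W) with inactive blocks at zero; also returns the
## observation residuals (log counts minus linear predictor), which drive
## the stratum-dispersion updates.
.drawEffects <- function(hyper, prep, mu_sd = 10) {
  ed <- .effectDesign(hyper, prep)
  cond <- .conditionalEffects(hyper, prep, mu_sd, ed = ed)
  z <- rnorm(length(cond$mean))
  u <- cond$mean + backsolve(cond$cholQ, z)
  eff <- .expandEffects(u, cond$layout, prep)
  eff$resid <- prep$r - drop(ed$A %*% u)
  eff
}

.expandEffects <- function(u, lay, prep) {
  P <- prep$P; S <- prep$S
  b <- u[seq_len(lay$k_b)]
  at <- lay$k_b
  w0 <- numeric(S)
  if (lay$act0) { w0 <- u[at + seq_len(S)]; at <- at + S }
  W <- matrix(0, S, P)
  for (j in seq_along(lay$actW)) {
    W[, lay$actW[j]] <- u[at + seq_len(S)]
    at <- at + S
  }
  list(mu0 = b[1L], mu_beta = b[-1L], w0 = w0, W = W)
}

## Prior draw of the Gaussian layer (used when the likelihood is masked).
.priorEffects <- function(hyper, prep, mu_sd = 10) {
  b <- rnorm(1L + prep$P, 0, mu_sd)
  w0 <- numeric(prep$S)
  if (hyper$sigma_beta0 > 0) {
    K0 <- exp(-hyper$phi0^2 * prep$D^2)
    w0 <- hyper$sigma_beta0 *
      drop(t(.cholJitter(K0, "K0")) %*% rnorm(prep$S))
  }
  W <- matrix(0, prep$S, prep$P)
  act <- which(hyper$sigma_beta > 0)
  if (length(act)) {
    KB <- exp(-hyper$phiB^2 * prep$D^2)
    s <- hyper$sigma_beta[act]
    Tm <- tcrossprod(s) * hyper$rho[act, act, drop = FALSE]
    Z <- matrix(rnorm(prep$S * length(act)), prep$S)
    W[, act] <- t(.cholJitter(KB, "KB")) %*% Z %*% .cholJitter(Tm, "T")
  }
  list(mu0 = b[1L], mu_beta = b[-1L], w0 = w0, W = W)
}
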