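## Spatial correlation kernels, the separable coefficient covariance and the
## matrix-normal density: the machinery behind the spatially varying
## coefficient fields.

#' Isotropic Gaussian spatial correlation
#'
#' Correlation between two strata a distance \eqn{d} apart is
#' \eqn{\exp(-\phi^2 d^2)}: unit correlation at zero distance, decaying
#' smoothly with a single decay parameter \code{phi} (units 1/km when
#' distances are in km).
#'
#' @param phi positive decay parameter (1/km).
#' @param D symmetric nonnegative distance matrix with zero diagonal (km), or
#'   a numeric vector/scalar of distances.
#' @return matrix (or vector) of correlations in (0, 1].
#' @examples
#' gaussianCorrelation(0.002, matrix(c(0, 100, 100, 0), 2))
#' @export
gaussianCorrelation <- function(phi, D) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("phi must be a single positive number")
  if (is.matrix(D)) .checkDistance(D)
  else if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0))
    stop("distances must be finite and nonnegative")
  exp(-phi^2 * D^2)
}

#' Among-predictor covariance from scales and a correlation matrix
#'
#' The coefficient fields of the different predictors share a covariance
#' \eqn{T = diag(\sigma_\beta) \rho \, diag(\sigma_\beta)}: per-predictor
#' spatial standard deviations and a correlation matrix among the predictors,
#' estimated independently.
#'
#' @param sigma_beta vector of positive per-predictor standard deviations.
#' @param rho correlation matrix among predictors (symmetric positive
#'   definite, unit diagonal).
#' @return covariance matrix \code{T} with \code{dimnames} taken from
#'   \code{names(sigma_beta)}.
#' @seealso [splitT()] for the inverse decomposition.
#' @export
buildT <- function(sigma_beta, rho) {
  if (any(!is.finite(sigma_beta)) || any(sigma_beta <= 0))
    stop("sigma_beta must be positive")
  .checkCorrelation(rho)
  if (length(sigma_beta) != nrow(rho))
    stop("length(sigma_beta) must match dim(rho)")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("rho must be positive definite")
  Tm <- diag(sigma_beta, length(sigma_beta)) %*% rho %*%
    diag(sigma_beta, length(sigma_beta))
  Tm <- (Tm + t(Tm)) / 2
  dimnames(Tm) <- list(names(sigma_beta), names(sigma_beta))
  Tm
}

#' Decompose a coefficient covariance into scales and correlation
#'
#' @param T positive-definite covariance matrix.
#' @return list with elements \code{sigma_beta} (sqrt of the diagonal) and
#'   \code{rho} (the implied correlation matrix).
#' @export
splitT <- function(T) {
  .checkSymmetric(T, "T")
  s <- sqrt(diag(T))
  if (any(s <= 0)) stop("T must have a positive diagonal")
  rho <- T / tcrossprod(s)
  diag(rho) <- 1
  list(sigma_beta = s, rho = rho)
}

#' Zero-mean matrix normal log-density
#'
#' Density of a strata-by-predictor matrix \code{W} under the matrix normal
#' with row (spatial) covariance \code{K} and column (among-predictor)
#' covariance \code{T}.  Equivalent to the multivariate normal density of the
#' row-major vectorization of \code{W} under the Kronecker covariance
#' \eqn{K \otimes T}, but evaluated via the two small factors:
#' \deqn{-\tfrac{SP}{2}\log 2\pi - \tfrac{P}{2}\log|K| - \tfrac{S}{2}\log|T|
#'       - \tfrac12 \mathrm{tr}(K^{-1} W T^{-1} W^\top).}
#'
#' @param W numeric matrix (S strata rows, P predictor columns).
#' @param K S-by-S positive-definite spatial matrix.
#' @param T P-by-P positive-definite among-predictor covariance.
#' @return the log-density (scalar).
#' @export
matrixNormalLogpdf <- function(W, K, T) {
  if (!is.matrix(W)) W <- as.matrix(W)
  S <- nrow(W); P <- ncol(W)
  .checkSymmetric(K, "K"); .checkSymmetric(T, "T")
  if (nrow(K) != S || nrow(T) != P)
    stop("dimensions of W, K and T do not conform")
  RK <- .cholJitter(K, "K")
  RT <- .cholJitter(T, "T")
  ## tr(K^-1 W T^-1 W') = || RK^-T W RT^-1 ||_F^2
  A <- backsolve(RK, W, transpose = TRUE)      # RK^-T W
  B <- t(backsolve(RT, t(A), transpose = TRUE)) # A RT^-1
  -0.5 * (S * P * log(2 * pi) + P * .logdetChol(RK) + S * .logdetChol(RT) +
            sum(B * B))
}

#' LKJ log-density over correlation matrices
#'
#' The C-vine construction of Lewandowski, Kurowicka and Joe with shape
#' \code{eta}; \code{eta = 1} is the uniform density over the space of valid
#' correlation matrices (constant w.r.t. Lebesgue measure on the
#' off-diagonal entries), the prior used for the among-predictor correlation.
#' The full normalizing constant is included, so for d = 2 and
#' \code{eta = 1} the value is \code{log(1/2)}.
#'
#' @param rho correlation matrix.
#' @param eta positive shape; 1 gives the flat prior.
#' @return log-density (scalar); \code{-Inf} for a non-positive-definite
#'   \code{rho}.
#' @export
lkjLogpdf <- function(rho, eta = 1) {
  .checkCorrelation(rho)
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0)
    stop("eta must be a single positive number")
  d <- nrow(rho)
  if (d == 1L) return(0)
  R <- tryCatch(chol(rho), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  ## log normalizing constant, Lewandowski et al. (2009)
  k <- seq_len(d - 1L)
  logc <- sum((2 * eta - 2 + d - k) * (d - k) * log(2) +
                (d - k) * lbeta(eta + (d - k - 1) / 2, eta + (d - k - 1) / 2))
  (eta - 1) * logdet - logc
}
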