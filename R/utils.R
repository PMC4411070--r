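## Internal numerical helpers shared across modules.

#' Cholesky factorization with escalating diagonal jitter
#'
#' Gaussian spatial kernels are notoriously ill-conditioned when the decay
#' parameter is small relative to the inter-point distances, so a plain
#' \code{chol()} can fail on matrices that are positive definite in exact
#' arithmetic.  This helper retries with a diagonal jitter escalating from
#' \code{1e-10} to \code{1e-6} (relative to the mean diagonal) and fails with
#' a condition-number report beyond that.
#'
#' @param M symmetric matrix expected to be positive definite.
#' @param label character used in error messages.
#' @return upper-triangular Cholesky factor, \code{t(R) %*% R == M} (up to
#'   the jitter actually applied, recorded in attribute \code{"jitter"}).
#' @keywords internal
.cholJitter <- function(M, label = "matrix") {
  jitters <- c(0, 1e-10, 1e-8, 1e-6)
  scale <- mean(diag(M))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  for (j in jitters) {
    R <- tryCatch(chol(M + diag(j * scale, nrow(M))), error = function(e) NULL)
    if (!is.null(R)) {
      attr(R, "jitter") <- j
      return(R)
    }
  }
  ev <- tryCatch(range(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) c(NA_real_, NA_real_))
  stop(sprintf(
    "Cholesky of %s failed after jitter escalation to 1e-6 (n = %d, eigenvalue range [%.3e, %.3e])",
    label, nrow(M), ev[1], ev[2]))
}

## log|det| from an upper Cholesky factor
.logdetChol <- function(R) 2 * sum(log(diag(R)))

#' Multivariate normal log-density (zero mean), used internally and by the
#' marginal likelihood.
#' @keywords internal
.mvnLogpdf0 <- function(x, Sigma, label = "covariance") {
  R <- .cholJitter(Sigma, label)
  z <- backsolve(R, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + .logdetChol(R) + sum(z * z))
}

.isSquare <- function(M) is.matrix(M) && nrow(M) == ncol(M)

.checkSymmetric <- function(M, label, tol = 1e-8) {
  if (!.isSquare(M))
    stop(sprintf("%s must be a square matrix", label))
  if (!all(is.finite(M)))
    stop(sprintf("%s contains non-finite entries", label))
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M))))
    stop(sprintf("%s must be symmetric", label))
  invisible(TRUE)
}

.checkCorrelation <- function(rho, label = "rho", tol = 1e-8) {
  .checkSymmetric(rho, label, tol)
  if (max(abs(diag(rho) - 1)) > tol)
    stop(sprintf("%s must have a unit diagonal", label))
  if (max(abs(rho)) > 1 + tol)
    stop(sprintf("%s entries must lie in [-1, 1]", label))
  invisible(TRUE)
}

.checkDistance <- function(D, label = "D") {
  .checkSymmetric(D, label)
  if (any(D < 0))
    stop(sprintf("%s must be nonnegative", label))
  if (max(abs(diag(D))) > 1e-12 * max(1, max(D)))
    stop(sprintf("%s must have a zero diagonal", label))
  invisible(TRUE)
}

## quantile rule used for all posterior summaries: linear interpolation of
## order statistics (type 7), recorded in output metadata for reproducibility
.QUANTILE_TYPE <- 7L
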