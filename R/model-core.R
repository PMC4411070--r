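## The joint model: lognormal observation layer, spatially varying linear
## predictor, priors, and the full log-posterior.

#' Construct an SVCParameters object
#'
#' @param mu0 global intercept.
#' @param mu_beta named vector of global (mean) coefficients, one per
#'   non-intercept predictor.
#' @param w0 stratum intercept deviations.
#' @param W stratum x predictor coefficient deviations.
#' @param sigma_beta0 intercept field scale.
#' @param sigma_beta per-predictor field scales.
#' @param tau per-stratum lognormal dispersions (log scale sd).
#' @param rho among-predictor correlation matrix.
#' @param phi0,phiB spatial decay parameters (1/km) of the intercept and
#'   coefficient fields.
#' @return an \linkS4class{SVCParameters}.
#' @export
SVCParameters <- function(mu0, mu_beta, w0, W, sigma_beta0, sigma_beta,
                          tau, rho, phi0, phiB) {
  new("SVCParameters", mu0 = as.numeric(mu0), mu_beta = mu_beta,
      w0 = as.numeric(w0), W = as.matrix(W),
      sigma_beta0 = as.numeric(sigma_beta0),
      sigma_beta = as.numeric(sigma_beta), tau = as.numeric(tau),
      rho = as.matrix(rho), phi0 = as.numeric(phi0), phiB = as.numeric(phiB))
}

setMethod("show", "SVCParameters", function(object) {
  cat(sprintf(
    "SVCParameters: %d strata, %d predictors\n  mu0 = %.3f; phi0 = %.4g, phiB = %.4g (1/km)\n",
    length(object@w0), length(object@mu_beta), object@mu0, object@phi0,
    object@phiB))
  cat("  mu_beta:", paste(sprintf("%s=%.3f", names(object@mu_beta),
                                  object@mu_beta), collapse = " "), "\n")
})

#' Linear predictor of log pond abundance
#'
#' \deqn{\mu_{s,t} = (\mu_0 + w_{0,s}) + \sum_p (\mu_{\beta,p} + w_{s,p})
#'   x_{s,t,p} + \log(\mathrm{area}_s)}
#' summed over the non-intercept predictors.  Years whose design entries are
#' undefined (the lag-source first year) come back \code{NA}.
#'
#' @param params an \linkS4class{SVCParameters}.
#' @param panel a \linkS4class{PondPanel}.
#' @return stratum x year matrix of expected log abundance.
#' @export
linearPredictor <- function(params, panel) {
  stopifnot(is(params, "SVCParameters"), is(panel, "PondPanel"))
  pn <- predictorNames(panel)
  S <- nrow(panel); Y <- ncol(panel)
  if (length(params@w0) != S || ncol(params@W) != length(pn))
    stop("parameter dimensions do not match the panel")
  mu <- matrix(params@mu0 + params@w0 + offsetLogArea(panel), S, Y)
  for (k in seq_along(pn)) {
    Xk <- SummarizedExperiment::assay(panel, pn[k])
    mu <- mu + (params@mu_beta[k] + params@W[, k]) * Xk
  }
  dimnames(mu) <- dimnames(pondCounts(panel))
  mu
}

#' Lognormal observation log-likelihood
#'
#' Sum over the modeled stratum-year cells of the lognormal log-density of
#' the pond count with log-scale mean \code{mu[s,t]} and log-scale sd
#' \code{tau[s]}.  When the panel carries a lag predictor the first year is
#' only the lag source and is excluded.
#'
#' @param panel a \linkS4class{PondPanel}.
#' @param mu stratum x year matrix of expected log abundance.
#' @param tau positive per-stratum log-scale standard deviations.
#' @return scalar log-likelihood.
#' @export
observationLoglik <- function(panel, mu, tau) {
  ponds <- pondCounts(panel)
  if (any(ponds <= 0)) stop("pond counts must be strictly positive")
  if (any(tau <= 0)) stop("tau must be positive")
  yrs <- modeledYears(panel)
  sum(dlnorm(ponds[, yrs, drop = FALSE],
             meanlog = mu[, yrs, drop = FALSE],
             sdlog = tau, log = TRUE))
}

#' Uniform prior bounds for the spatial decay parameters
#'
#' The bounds are chosen so that the Gaussian kernel can span from a
#' correlation of \code{c_high} at the largest inter-stratum distance down
#' to \code{c_low} at the smallest: \code{lower = sqrt(-log(c_high))/d_max},
#' \code{upper = sqrt(-log(c_low))/d_min}.
#'
#' @param D distance matrix (km) or a \linkS4class{StrataGeometry}.
#' @param c_low,c_high target correlations, \code{0 < c_low < c_high < 1}.
#' @return a \linkS4class{PhiBounds}.
#' @export
phiPriorBounds <- function(D, c_low = 0.01, c_high = 0.90) {
  if (is(D, "StrataGeometry")) D <- distanceMatrix(D)
  .checkDistance(D)
  if (nrow(D) < 2L) stop("need at least two strata")
  if (!(c_low > 0 && c_low < c_high && c_high < 1))
    stop("need 0 < c_low < c_high < 1")
  off <- D[upper.tri(D)]
  d_min <- min(off); d_max <- max(off)
  if (d_min <= 0) stop("degenerate geometry: two strata at zero distance")
  new("PhiBounds", lower = sqrt(-log(c_high)) / d_max,
      upper = sqrt(-log(c_low)) / d_min)
}

setMethod("show", "PhiBounds", function(object) {
  cat(sprintf("PhiBounds: [%.4g, %.4g] 1/km\n", object@lower, object@upper))
})

## Hyperprior terms only (no random-effect fields): Normal(0, 10) means,
## Gamma(1.2, 0.2) scales, LKJ(1) correlation, Uniform phi.
.logHyperPrior <- function(params, bounds, prior = priorConfig()) {
  if (params@phi0 < bounds@lower || params@phi0 > bounds@upper ||
      params@phiB < bounds@lower || params@phiB > bounds@upper)
    return(structure(-Inf, reason = "phi outside its uniform prior bounds"))
  if (params@sigma_beta0 <= 0 || any(params@sigma_beta <= 0))
    return(structure(-Inf, reason = "nonpositive scale parameter"))
  lp <- sum(dnorm(c(params@mu0, params@mu_beta), 0, prior$mu_sd, log = TRUE)) +
    sum(dgamma(c(params@sigma_beta0, params@sigma_beta, params@tau),
               shape = prior$gamma_shape, rate = prior$gamma_rate,
               log = TRUE)) +
    lkjLogpdf(params@rho, eta = prior$lkj_eta) -
    2 * log(bounds@upper - bounds@lower)
  lp
}

#' Prior settings
#'
#' Default hyperpriors: Normal(0, sd 10) on the global mean effects,
#' Gamma(shape 1.2, rate 0.2) on every scale (field scales and stratum
#' dispersions), LKJ(1) (uniform) on the among-predictor correlation, and
#' Uniform on the spatial decay parameters between the bounds implied by the
#' geometry (see [phiPriorBounds()]).
#'
#' @param mu_sd normal prior sd of the mean effects.
#' @param gamma_shape,gamma_rate Gamma prior of all scale parameters.
#' @param lkj_eta LKJ shape of the correlation prior.
#' @param c_low,c_high kernel correlations defining the phi bounds.
#' @return a list of prior settings.
#' @export
priorConfig <- function(mu_sd = 10, gamma_shape = 1.2, gamma_rate = 0.2,
                        lkj_eta = 1, c_low = 0.01, c_high = 0.90) {
  list(mu_sd = mu_sd, gamma_shape = gamma_shape, gamma_rate = gamma_rate,
       lkj_eta = lkj_eta, c_low = c_low, c_high = c_high)
}

#' Log-prior of the model parameters
#'
#' Hyperpriors (see [priorConfig()]) plus, when a geometry is supplied, the
#' Gaussian field terms: the intercept deviations \code{w0} under
#' \eqn{MVN(0, \sigma_{\beta 0}^2 K_0(\phi_0))} and the coefficient
#' deviations \code{W} under the matrix normal with row covariance
#' \eqn{K_B(\phi_B)} and column covariance \eqn{T(\sigma_\beta, \rho)}.
#' Out-of-support parameters return \code{-Inf} carrying a \code{"reason"}
#' attribute.
#'
#' @param params an \linkS4class{SVCParameters}.
#' @param bounds a \linkS4class{PhiBounds}.
#' @param geometry optionally a \linkS4class{StrataGeometry}; when supplied
#'   the random-effect field densities are included.
#' @param prior prior settings from [priorConfig()].
#' @return scalar log-density.
#' @export
logPrior <- function(params, bounds, geometry = NULL, prior = priorConfig()) {
  lp <- .logHyperPrior(params, bounds, prior)
  if (!is.finite(lp) || is.null(geometry)) return(lp)
  D <- distanceMatrix(geometry)
  K0 <- gaussianCorrelation(params@phi0, D)
  lp <- lp + .mvnLogpdf0(params@w0, params@sigma_beta0^2 * K0, "sigma0^2 K0")
  KB <- gaussianCorrelation(params@phiB, D)
  Tm <- buildT(params@sigma_beta, params@rho)
  lp + matrixNormalLogpdf(params@W, KB, Tm)
}

#' Joint log-posterior
#'
#' \code{logPrior} (hyperpriors plus both random-effect field densities)
#' plus the lognormal observation log-likelihood at the linear predictor.
#'
#' @inheritParams logPrior
#' @param panel a \linkS4class{PondPanel}.
#' @return scalar log-density; \code{-Inf} outside the support.
#' @export
logPosterior <- function(params, panel, geometry = strataGeometry(panel),
                         bounds = phiPriorBounds(geometry),
                         prior = priorConfig()) {
  lp <- logPrior(params, bounds, geometry, prior)
  if (!is.finite(lp)) return(lp)
  mu <- linearPredictor(params, panel)
  lp + observationLoglik(panel, mu, params@tau)
}
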