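## Derived ecological quantities, propagated draw-by-draw over the
## posterior: effective spatial ranges, variance decomposition, density and
## coefficient-of-variation transforms.

#' Effective spatial range
#'
#' Distance at which the Gaussian kernel decays to \code{threshold}:
#' \eqn{d = \sqrt{-\ln(\mathrm{threshold})}/\phi}, so
#' \code{gaussianCorrelation(phi, effectiveRange(phi))} equals the threshold
#' exactly.
#'
#' @param phi positive decay parameter (1/km); vectorized.
#' @param threshold correlation level in (0, 1]; default 0.05.
#' @return distance in km.
#' @export
effectiveRange <- function(phi, threshold = 0.05) {
  if (any(phi <= 0)) stop("phi must be positive")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  sqrt(-log(threshold)) / phi
}

#' Per-stratum variance decomposition
#'
#' Fraction of the within-stratum variance of log pond abundance accounted
#' for by each predictor:
#' \deqn{p_{s,p} = \frac{B_{s,p}^2 \,\mathrm{Var}(x_{s,\cdot,p})}
#'   {\sum_k B_{s,k}^2 \,\mathrm{Var}(x_{s,\cdot,k}) + \tau_s^2}}
#' where \eqn{B_{s,p}} is the stratum's total coefficient and the variance
#' is the sample variance of the realized predictor series over the modeled
#' years.  The fractions plus the residual share
#' \eqn{\tau_s^2/(\mathrm{denominator})} partition one exactly.  A
#' zero-variance predictor contributes zero (not NaN).
#'
#' @param B_s total coefficient vector of the stratum (non-intercept).
#' @param X_s years x predictor matrix of that stratum's realized predictor
#'   series (or a precomputed variance vector via \code{x_var}).
#' @param tau_s positive stratum dispersion.
#' @param x_var optional per-predictor variances, bypassing \code{X_s}.
#' @return named vector of fractions with attribute \code{"residual"}.
#' @export
varianceExplained <- function(B_s, X_s = NULL, tau_s, x_var = NULL) {
  if (tau_s < 0) stop("tau_s must be nonnegative")
  if (is.null(x_var)) {
    X_s <- as.matrix(X_s)
    if (nrow(X_s) < 2L) stop("need at least two modeled years")
    x_var <- apply(X_s, 2L, var)
  }
  if (length(B_s) != length(x_var))
    stop("B_s and predictor variances must conform")
  num <- B_s^2 * x_var
  den <- sum(num) + tau_s^2
  if (den == 0) {
    out <- rep(0, length(num))
    attr(out, "residual") <- 1
    return(out)
  }
  out <- num / den
  attr(out, "residual") <- tau_s^2 / den
  out
}

#' Mean pond density and coefficient of variation
#'
#' Lognormal transforms of a stratum's offset-free intercept
#' \eqn{\beta_{0,s}} and dispersion \eqn{\tau_s}: mean density
#' \eqn{e^{\beta_0 + \tau^2/2}} per square km (the log-area offset makes the
#' intercept a log density; supply \code{area_km2} if the intercept instead
#' includes the log area), and the coefficient of variation
#' \eqn{\sqrt{e^{\tau^2} - 1}}.  The squared form \eqn{e^{\tau^2} - 1} is
#' available behind \code{squared = TRUE} for parity with map figures that
#' print it.
#'
#' @param beta0_s offset-free stratum intercept (log density scale).
#' @param tau_s positive dispersion.
#' @param area_km2 optional stratum area when \code{beta0_s} is on the
#'   abundance rather than density scale.
#' @param squared return the squared CV form.
#' @return list with \code{density} (per square km) and \code{cv}.
#' @export
densityAndCV <- function(beta0_s, tau_s, area_km2 = NULL, squared = FALSE) {
  if (any(tau_s <= 0)) stop("tau_s must be positive")
  density <- exp(beta0_s + tau_s^2 / 2)
  if (!is.null(area_km2)) density <- density / area_km2
  cv2 <- exp(tau_s^2) - 1
  list(density = density, cv = if (squared) cv2 else sqrt(cv2))
}

#' Derived quantities over the posterior
#'
#' Every derived quantity is computed for each posterior draw and then
#' summarized (median and central 95% interval) -- never from
#' posterior-median parameters.
#'
#' @param draws a \linkS4class{PosteriorDraws} from [runMCMC()].
#' @param panel the fitted \linkS4class{PondPanel}.
#' @param squared_cv report the squared CV form.
#' @return a \linkS4class{DerivedSummary}.
#' @export
deriveOverPosterior <- function(draws, panel, squared_cv = FALSE) {
  m <- drawsMatrix(draws)
  pn <- predictorNames(panel)
  ids <- rownames(panel)
  S <- length(ids); P <- length(pn)
  yrs <- modeledYears(panel)
  X <- designArray(panel)[, yrs, -1L, drop = FALSE]
  x_var <- apply(X, c(1L, 3L), var)          # S x P realized variances
  nd <- nrow(m)
  qs <- function(v) quantile(v, c(0.5, 0.025, 0.975), type = .QUANTILE_TYPE,
                             names = FALSE)

  q0 <- qs(effectiveRange(m[, "phi0"]))
  qB <- qs(effectiveRange(m[, "phiB"]))
  effective_range <- data.frame(
    quantity = c("intercept", "coefficients"),
    median = c(q0[1], qB[1]), ci_lo = c(q0[2], qB[2]),
    ci_hi = c(q0[3], qB[3]))

  mu_beta <- m[, sprintf("mu_beta[%s]", pn), drop = FALSE]
  tauM <- m[, sprintf("tau[%s]", ids), drop = FALSE]
  vp <- array(NA_real_, c(nd, S, P + 1L))
  for (s in seq_len(S)) {
    Bs <- mu_beta + m[, sprintf("W[%s,%s]", ids[s], pn), drop = FALSE]
    num <- sweep(Bs^2, 2L, x_var[s, ], "*")
    den <- rowSums(num) + tauM[, s]^2
    vp[, s, seq_len(P)] <- num / den
    vp[, s, P + 1L] <- tauM[, s]^2 / den
  }
  variance_proportions <- do.call(rbind, lapply(seq_len(S), function(s) {
    q <- apply(vp[, s, , drop = FALSE], 3L, qs)
    data.frame(stratum = ids[s], predictor = c(pn, "residual"),
               median = q[1, ], ci_lo = q[2, ], ci_hi = q[3, ],
               row.names = NULL)
  }))

  density_cv <- do.call(rbind, lapply(seq_len(S), function(s) {
    b0 <- m[, "mu0"] + m[, sprintf("w0[%s]", ids[s])]
    dc <- densityAndCV(b0, tauM[, s], squared = squared_cv)
    qd <- qs(dc$density); qc <- qs(dc$cv)
    data.frame(stratum = ids[s],
               quantity = c("density_km2", "cv"),
               median = c(qd[1], qc[1]), ci_lo = c(qd[2], qc[2]),
               ci_hi = c(qd[3], qc[3]), row.names = NULL)
  }))

  new("DerivedSummary", effective_range = effective_range,
      variance_proportions = variance_proportions, density_cv = density_cv,
      meta = list(n_draws = nd, quantile_type = .QUANTILE_TYPE,
                  cv_form = if (squared_cv) "exp(tau^2)-1" else
                    "sqrt(exp(tau^2)-1)"))
}

setMethod("show", "DerivedSummary", function(object) {
  cat("DerivedSummary over", object@meta$n_draws, "posterior draws\n")
  er <- object@effective_range
  for (i in seq_len(nrow(er)))
    cat(sprintf("  effective range (%s): %.0f km (95%% CI %.0f-%.0f)\n",
                er$quantity[i], er$median[i], er$ci_lo[i], er$ci_hi[i]))
  cat(sprintf("  variance proportions: %d strata x %d components\n",
              length(unique(object@variance_proportions$stratum)),
              length(unique(object@variance_proportions$predictor))))
})
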