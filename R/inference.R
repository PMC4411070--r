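## Posterior computation: adaptive block Metropolis over the marginal
## likelihood of the hyperparameters, exact conditional draws of the
## Gaussian layer, split-Rhat diagnostics and posterior summaries.

#' Sampler control settings
#'
#' @param likelihood logical; \code{FALSE} masks the likelihood so the
#'   sampler explores the prior only (prior-recovery checks).
#' @param fixed named list of hyperparameters to hold fixed rather than
#'   sample: any of \code{tau} (vector), \code{sigma_beta0},
#'   \code{sigma_beta} (vector), \code{rho} (matrix), \code{phi0},
#'   \code{phiB}.  Fixed scales may be zero, which switches the
#'   corresponding random-effect field off entirely.
#' @param target_accept named acceptance-rate targets for the three proposal
#'   blocks.
#' @param init_retries attempts at finding a finite starting point.
#' @return list of control settings.
#' @export
mcmcControl <- function(likelihood = TRUE, fixed = list(),
                        target_accept = c(sigma = 0.25, rho = 0.25,
                                          phi = 0.40),
                        init_retries = 10L) {
  list(likelihood = likelihood, fixed = fixed, target_accept = target_accept,
       init_retries = as.integer(init_retries))
}

#' Fit the spatially varying coefficient model
#'
#' Partially collapsed MCMC: the Gaussian layers (global means, intercept
#' field, coefficient field) are integrated out analytically; the field
#' scales, among-predictor correlation and spatial decay parameters are
#' sampled with adaptive block random-walk Metropolis against that marginal
#' likelihood (log scale for standard deviations, logit between the uniform
#' bounds for the decay parameters, raw off-diagonals with a
#' positive-definiteness rejection for the correlation -- exact under the
#' flat LKJ(1) prior); the Gaussian layer is then redrawn exactly from its
#' conditional every sweep and the stratum dispersions are slice-sampled
#' given the resulting residuals.  The draws target the full joint
#' posterior.  Proposal scales and covariances adapt during warmup only.
#'
#' @param panel a \linkS4class{PondPanel}.
#' @param geometry a \linkS4class{StrataGeometry}; defaults to the panel's.
#' @param chains number of chains (run sequentially).
#' @param warmup warmup iterations per chain (discarded).
#' @param kept kept iterations per chain.
#' @param thin sweeps between kept iterations (warmup is scaled by the same
#'   factor so adaptation sees comparable effort).
#' @param seed integer seed; the full run is deterministic given it.
#' @param prior prior settings, see [priorConfig()].
#' @param control sampler settings, see [mcmcControl()].
#' @return a \linkS4class{PosteriorDraws}.
#' @export
runMCMC <- function(panel, geometry = strataGeometry(panel), chains = 5L,
                    warmup = 400L, kept = 2000L, thin = 1L, seed = 1L,
                    prior = priorConfig(), control = mcmcControl()) {
  stopifnot(is(panel, "PondPanel"), chains >= 1L, kept >= 1L, thin >= 1L)
  set.seed(as.integer(seed))
  prep <- .prepPanel(panel, geometry)
  bounds <- phiPriorBounds(distanceMatrix(geometry), prior$c_low, prior$c_high)
  spec <- .samplerSpec(prep, bounds, prior, control)

  nms <- .parameterNames(panel)
  draws <- array(NA_real_, dim = c(chains, kept, length(nms)),
                 dimnames = list(NULL, NULL, nms))
  accept <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res <- .runChain(spec, prep, warmup = warmup * thin, kept = kept,
                     thin = thin, control = control)
    draws[ch, , ] <- res$draws
    accept[[ch]] <- res$accept
  }
  new("PosteriorDraws", draws = draws, parameter_names = nms,
      seed = as.integer(seed), warmup = as.integer(warmup),
      kept = as.integer(kept), thin = as.integer(thin),
      diagnostics = list(accept = accept, phi_bounds = c(bounds@lower,
                                                         bounds@upper),
                         quantile_type = .QUANTILE_TYPE,
                         likelihood = control$likelihood))
}

## ---- internal sampler machinery ------------------------------------------
##
## Partially collapsed Gibbs sweep:
##   1. adaptive random-walk Metropolis on (sigma_beta0, sigma_beta), rho and
##      (phi0, phiB), each against the marginal likelihood with the Gaussian
##      layer integrated out (conditioning on the current tau);
##   2. one exact conditional draw of the Gaussian layer;
##   3. univariate slice updates of each stratum dispersion tau_s given the
##      residuals (conjugate-free but cheap and tuning-free).
## Collapsing the layer out of the Metropolis steps removes the slow
## hierarchical coupling between field scales and field values.

.parameterNames <- function(panel) {
  pn <- predictorNames(panel)
  ids <- rownames(panel)
  rho_nms <- if (length(pn) >= 2L) {
    idx <- which(upper.tri(diag(length(pn))), arr.ind = TRUE)
    sprintf("rho[%s,%s]", pn[idx[, 1]], pn[idx[, 2]])
  } else character()
  c("mu0", sprintf("mu_beta[%s]", pn), sprintf("w0[%s]", ids),
    as.vector(outer(ids, pn, function(s, p) sprintf("W[%s,%s]", s, p))),
    "sigma_beta0", sprintf("sigma_beta[%s]", pn), sprintf("tau[%s]", ids),
    rho_nms, "phi0", "phiB")
}

## Describes the unconstrained Metropolis state vector and its blocks.
.samplerSpec <- function(prep, bounds, prior, control) {
  S <- prep$S; P <- prep$P
  fixed <- control$fixed
  free_s0 <- !("sigma_beta0" %in% names(fixed))
  free_sb <- !("sigma_beta" %in% names(fixed))
  free_rho <- !("rho" %in% names(fixed)) && P >= 2L
  free_p0 <- !("phi0" %in% names(fixed))
  free_pB <- !("phiB" %in% names(fixed))
  idx <- list(); at <- 0L
  add <- function(n) { out <- at + seq_len(n); at <<- at + n; out }
  if (free_s0) idx$sigma_beta0 <- add(1L)
  if (free_sb) idx$sigma_beta <- add(P)
  if (free_rho) idx$rho <- add(P * (P - 1L) / 2L)
  if (free_p0) idx$phi0 <- add(1L)
  if (free_pB) idx$phiB <- add(1L)
  blocks <- list()
  sc <- c(idx$sigma_beta0, idx$sigma_beta)
  if (length(sc)) blocks$sigma <- sc
  if (free_rho) blocks$rho <- idx$rho
  ph <- c(idx$phi0, idx$phiB)
  if (length(ph)) blocks$phi <- ph
  list(S = S, P = P, idx = idx, blocks = blocks, ntheta = at,
       free_tau = !("tau" %in% names(fixed)),
       bounds = bounds, prior = prior, fixed = fixed,
       uppertri = which(upper.tri(diag(max(P, 1L))), arr.ind = TRUE))
}

## theta (unconstrained Metropolis part) + tau -> hyperparameter list;
## NULL if a rho proposal leaves the positive-definite cone.
.unpackHyper <- function(theta, tau, spec) {
  fx <- spec$fixed; idx <- spec$idx
  lo <- spec$bounds@lower; up <- spec$bounds@upper
  s0 <- if (is.null(idx$sigma_beta0)) fx$sigma_beta0 else exp(theta[idx$sigma_beta0])
  sb <- if (is.null(idx$sigma_beta)) fx$sigma_beta else exp(theta[idx$sigma_beta])
  if (length(sb) == 1L && spec$P > 1L) sb <- rep(sb, spec$P)
  rho <- diag(spec$P)
  if (!is.null(idx$rho)) {
    z <- theta[idx$rho]
    if (max(abs(z)) >= 1) return(NULL)
    rho[spec$uppertri] <- z
    rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
    if (is.null(tryCatch(chol(rho), error = function(e) NULL))) return(NULL)
  } else if (!is.null(fx$rho)) rho <- fx$rho
  phi0 <- if (is.null(idx$phi0)) fx$phi0 else lo + (up - lo) * plogis(theta[idx$phi0])
  phiB <- if (is.null(idx$phiB)) fx$phiB else lo + (up - lo) * plogis(theta[idx$phiB])
  list(tau = tau, sigma_beta0 = s0, sigma_beta = sb, rho = rho,
       phi0 = phi0, phiB = phiB)
}

## log prior of the Metropolis-sampled hyperparameters on the unconstrained
## scale (Gamma + log Jacobian for scales, Uniform + logit Jacobian for phi,
## flat for rho within the positive-definite cone).
.logHyperTarget <- function(theta, hyper, spec) {
  pr <- spec$prior; idx <- spec$idx
  lp <- 0
  gpar <- function(v, lth) sum(dgamma(v, pr$gamma_shape, rate = pr$gamma_rate,
                                      log = TRUE)) + sum(lth)
  if (!is.null(idx$sigma_beta0))
    lp <- lp + gpar(hyper$sigma_beta0, theta[idx$sigma_beta0])
  if (!is.null(idx$sigma_beta))
    lp <- lp + gpar(hyper$sigma_beta, theta[idx$sigma_beta])
  lo <- spec$bounds@lower; up <- spec$bounds@upper
  for (nm in c("phi0", "phiB"))
    if (!is.null(idx[[nm]])) {
      ph <- hyper[[nm]]
      lp <- lp + log(ph - lo) + log(up - ph) - 2 * log(up - lo)
    }
  lp
}

.logTarget <- function(theta, tau, spec, prep, control) {
  hyper <- .unpackHyper(theta, tau, spec)
  if (is.null(hyper)) return(list(lp = -Inf, hyper = NULL))
  lp <- .logHyperTarget(theta, hyper, spec)
  if (control$likelihood)
    lp <- lp + .marginalLoglik(hyper, prep, spec$prior$mu_sd)
  list(lp = lp, hyper = hyper)
}

.initState <- function(spec, prep, control) {
  pr <- spec$prior
  ndraw <- function(n) log(qgamma(runif(n, 0.02, 0.5), pr$gamma_shape,
                                  rate = pr$gamma_rate))
  for (try in seq_len(control$init_retries)) {
    theta <- numeric(spec$ntheta)
    if (!is.null(spec$idx$sigma_beta0)) theta[spec$idx$sigma_beta0] <- ndraw(1L)
    if (!is.null(spec$idx$sigma_beta)) theta[spec$idx$sigma_beta] <- ndraw(spec$P)
    if (!is.null(spec$idx$rho)) theta[spec$idx$rho] <- 0
    if (!is.null(spec$idx$phi0)) theta[spec$idx$phi0] <- qlogis(runif(1, 0.2, 0.8))
    if (!is.null(spec$idx$phiB)) theta[spec$idx$phiB] <- qlogis(runif(1, 0.2, 0.8))
    tau <- if (spec$free_tau) {
      if (control$likelihood) {
        ## moment-matched start: per-stratum sd of year-to-year log changes
        y <- matrix(prep$y, prep$S, prep$M)
        tau0 <- apply(y, 1L, function(v) sd(diff(v)) / sqrt(2))
        pmin(pmax(tau0, 0.05), 5)
      } else exp(ndraw(prep$S))
    } else spec$fixed$tau
    cur <- .logTarget(theta, tau, spec, prep, control)
    if (is.finite(cur$lp)) return(list(theta = theta, tau = tau, cur = cur))
  }
  stop("MCMC initialization failed: log-posterior non-finite after retries")
}

## Univariate slice sampler (Neal 2003, stepping out + shrinkage) on an
## unbounded coordinate.
.sliceUpdate <- function(x0, logf, w = 0.5, m = 20L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  z <- f0 - rexp(1)
  L <- x0 - runif(1) * w
  Rr <- L + w
  j <- floor(runif(1) * m); k <- m - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(Rr) > z) { Rr <- Rr + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, Rr)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else Rr <- x1
  }
}

## Slice update of every stratum dispersion given the Gaussian layer:
## target on log tau_s combines the Gamma prior (with Jacobian) and the
## stratum residual sum of squares.
.updateTau <- function(tau, ss, spec, prep, control) {
  a <- spec$prior$gamma_shape; b <- spec$prior$gamma_rate
  M <- prep$M
  for (s in seq_len(prep$S)) {
    logf <- if (control$likelihood) {
      sss <- ss[s]
      function(lt) a * lt - b * exp(lt) - M * lt - sss / (2 * exp(2 * lt))
    } else function(lt) a * lt - b * exp(lt)
    tau[s] <- exp(.sliceUpdate(log(tau[s]), logf))
  }
  tau
}

## Interweaved conditional updates: slice moves on the field scales,
## among-predictor correlation and decay parameters given the freshly drawn
## field values.  These conditionals involve only S x S and P x P matrices,
## so they are near-free, and they complement the marginal Metropolis
## blocks: the conditionals mix fast where the fields are well identified,
## the marginal moves handle the small-scale (funnel) regime.
.interweave <- function(theta, tau, spec, prep, control, eff) {
  idx <- spec$idx; pr <- spec$prior
  a <- pr$gamma_shape; b <- pr$gamma_rate
  lo <- spec$bounds@lower; up <- spec$bounds@upper
  D2m <- prep$D^2
  S <- prep$S; P <- spec$P
  cur_sb <- function() if (is.null(idx$sigma_beta)) spec$fixed$sigma_beta
                       else exp(theta[idx$sigma_beta])
  cur_rho <- function() {
    rho <- diag(P)
    if (!is.null(idx$rho)) {
      rho[spec$uppertri] <- theta[idx$rho]
      rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
    } else if (!is.null(spec$fixed$rho)) rho <- spec$fixed$rho
    rho
  }
  cur_phiB <- function() if (is.null(idx$phiB)) spec$fixed$phiB
                         else lo + (up - lo) * plogis(theta[idx$phiB])
  cur_phi0 <- function() if (is.null(idx$phi0)) spec$fixed$phi0
                         else lo + (up - lo) * plogis(theta[idx$phi0])
  ## matrix-normal kernel in T given the spatial sufficient statistic
  ## G = W' KB^-1 W (precomputed once per sweep): up to constants,
  ## -(S/2) log|T| - tr(T^-1 G)/2.
  mnT <- function(sb, rho, G) {
    Tm <- tcrossprod(sb) * rho
    RT <- tryCatch(chol(Tm), error = function(e) NULL)
    if (is.null(RT)) return(-Inf)
    -S * sum(log(diag(RT))) - 0.5 * sum(chol2inv(RT) * G)
  }
  ## intercept field: scale then decay, given w0
  if (any(eff$w0 != 0)) {
    if (!is.null(idx$sigma_beta0)) {
      K0 <- exp(-cur_phi0()^2 * D2m)
      q0 <- sum(backsolve(.cholJitter(K0, "K0"), eff$w0, transpose = TRUE)^2)
      logf <- function(ls) a * ls - b * exp(ls) - S * ls - q0 / (2 * exp(2 * ls))
      theta[idx$sigma_beta0] <- .sliceUpdate(theta[idx$sigma_beta0], logf)
    }
    if (!is.null(idx$phi0)) {
      s0 <- if (is.null(idx$sigma_beta0)) spec$fixed$sigma_beta0
            else exp(theta[idx$sigma_beta0])
      logf <- function(u) {
        ph <- lo + (up - lo) * plogis(u)
        lp <- tryCatch(.mvnLogpdf0(eff$w0, s0^2 * exp(-ph^2 * D2m), "K0"),
                       error = function(e) -Inf)
        lp + log(ph - lo) + log(up - ph)
      }
      theta[idx$phi0] <- .sliceUpdate(theta[idx$phi0], logf, w = 1)
    }
  }
  ## coefficient field: per-predictor scales, correlations, decay, given W
  if (any(eff$W != 0)) {
    KB <- exp(-cur_phiB()^2 * D2m)
    RKB <- .cholJitter(KB, "KB")
    G <- crossprod(backsolve(RKB, eff$W, transpose = TRUE))
    if (!is.null(idx$sigma_beta)) {
      rho <- cur_rho()
      for (p in seq_len(P)) {
        sb <- cur_sb()
        logf <- function(ls) {
          sb[p] <- exp(ls)
          mnT(sb, rho, G) + a * ls - b * exp(ls)
        }
        theta[idx$sigma_beta[p]] <- .sliceUpdate(theta[idx$sigma_beta[p]], logf)
      }
    }
    if (!is.null(idx$rho)) {
      sb <- cur_sb()
      for (j in seq_along(idx$rho)) {
        rho <- cur_rho()
        ij <- spec$uppertri[j, ]
        logf <- function(z) {
          if (abs(z) >= 1) return(-Inf)
          rho[ij[1], ij[2]] <- z; rho[ij[2], ij[1]] <- z
          ## chol failure inside mnT enforces the same positive-definite
          ## support as the Metropolis state
          if (is.null(tryCatch(chol(rho), error = function(e) NULL)))
            return(-Inf)
          mnT(sb, rho, G)
        }
        theta[idx$rho[j]] <- .sliceUpdate(theta[idx$rho[j]], logf, w = 0.25)
      }
    }
    if (!is.null(idx$phiB)) {
      sb <- cur_sb(); rho <- cur_rho()
      Tm <- tcrossprod(sb) * rho
      H <- eff$W %*% chol2inv(.cholJitter(Tm, "T")) %*% t(eff$W)
      logf <- function(u) {
        ph <- lo + (up - lo) * plogis(u)
        RK <- tryCatch(chol(exp(-ph^2 * D2m) + diag(1e-10, S)),
                       error = function(e) NULL)
        if (is.null(RK)) return(-Inf)
        -P * sum(log(diag(RK))) - 0.5 * sum(chol2inv(RK) * H) +
          log(ph - lo) + log(up - ph)
      }
      theta[idx$phiB] <- .sliceUpdate(theta[idx$phiB], logf, w = 1)
    }
  }
  theta
}

.runChain <- function(spec, prep, warmup, kept, thin, control) {
  init <- .initState(spec, prep, control)
  theta <- init$theta; tau <- init$tau; cur <- init$cur
  blocks <- spec$blocks
  nb <- length(blocks)
  lsc <- lapply(blocks, function(b) log(0.3 / sqrt(length(b))))
  targ <- control$target_accept
  mom <- lapply(blocks, function(b)
    list(n = 0, mean = numeric(length(b)),
         M2 = matrix(0, length(b), length(b)), L = NULL))
  nacc <- nprop <- setNames(numeric(max(nb, 1L)), names(blocks))
  total <- warmup + kept * thin
  npar <- 1L + spec$P + prep$S + prep$S * spec$P + 1L + spec$P + prep$S +
    (if (spec$P >= 2L) (spec$P * (spec$P - 1L)) %/% 2L else 0L) + 2L
  out <- matrix(NA_real_, kept, npar)
  krow <- 0L
  for (it in seq_len(total)) {
    inWarm <- it <= warmup
    for (b in seq_len(nb)) {
      bi <- blocks[[b]]
      d <- length(bi)
      z <- rnorm(d)
      L <- mom[[b]]$L
      step <- if (is.null(L)) z else drop(L %*% z)
      prop <- theta
      prop[bi] <- prop[bi] + exp(lsc[[b]]) * step
      cand <- .logTarget(prop, tau, spec, prep, control)
      a <- cand$lp - cur$lp
      acc <- is.finite(a) && log(runif(1)) < a
      if (acc) { theta <- prop; cur <- cand }
      if (inWarm) {
        g <- min(0.25, 2 / it^0.6)
        lsc[[b]] <- lsc[[b]] + g * ((if (acc) 1 else 0) - targ[[names(blocks)[b]]])
        m <- mom[[b]]
        m$n <- m$n + 1
        dlt <- theta[bi] - m$mean
        m$mean <- m$mean + dlt / m$n
        m$M2 <- m$M2 + tcrossprod(dlt, theta[bi] - m$mean)
        if (d > 1L && m$n > 20L && m$n %% 25L == 0L) {
          cv <- m$M2 / (m$n - 1)
          m$L <- tryCatch(t(chol(cv + diag(1e-9 + 1e-6 * mean(diag(cv)), d))),
                          error = function(e) NULL)
        }
        mom[[b]] <- m
      } else {
        nacc[b] <- nacc[b] + acc
        nprop[b] <- nprop[b] + 1
      }
    }
    ## exact conditional draw of the Gaussian layer, then dispersions
    eff <- if (control$likelihood) .drawEffects(cur$hyper, prep, spec$prior$mu_sd)
           else .priorEffects(cur$hyper, prep, spec$prior$mu_sd)
    if (spec$free_tau) {
      ss <- if (control$likelihood)
        drop(rowsum(eff$resid^2, prep$si)) else numeric(prep$S)
      tau <- .updateTau(tau, ss, spec, prep, control)
    }
    theta <- .interweave(theta, tau, spec, prep, control, eff)
    cur <- .logTarget(theta, tau, spec, prep, control)
    if (!inWarm && (it - warmup) %% thin == 0L) {
      krow <- krow + 1L
      hyper <- cur$hyper
      rho_off <- if (spec$P >= 2L) hyper$rho[upper.tri(hyper$rho)] else numeric()
      out[krow, ] <- c(eff$mu0, eff$mu_beta, eff$w0, as.vector(eff$W),
                       hyper$sigma_beta0, hyper$sigma_beta, hyper$tau,
                       rho_off, hyper$phi0, hyper$phiB)
    }
  }
  list(draws = out, accept = nacc / pmax(nprop, 1))
}

## ---- diagnostics and summaries -------------------------------------------

#' @describeIn splitRhat matrix method: rows are chains, columns kept
#'   iterations.
#' @export
setMethod("splitRhat", "matrix", function(x, ...) {
  nch <- nrow(x); nit <- ncol(x)
  if (nit < 4L) stop("split-Rhat needs at least 4 kept iterations")
  half <- nit %/% 2L
  halves <- vector("list", 2L * nch)
  for (c in seq_len(nch)) {
    halves[[2 * c - 1]] <- x[c, seq_len(half)]
    halves[[2 * c]] <- x[c, half + seq_len(half)]
  }
  m <- length(halves); n <- half
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) {
    if (B <= 0) return(NA_real_)  # identical constant chains: undefined
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
})

#' @describeIn splitRhat per-parameter split potential scale reduction
#'   factor: each chain is split in half and the classic between/within
#'   variance ratio is computed over the resulting half-chains.  Constant
#'   identical chains give \code{NA} (flagged, not silently 1); chains stuck
#'   at different constants give \code{Inf}.
#' @export
setMethod("splitRhat", "PosteriorDraws", function(x, ...) {
  vapply(seq_along(x@parameter_names),
         function(j) {
           m <- x@draws[, , j, drop = FALSE]
           dim(m) <- dim(m)[1:2]
           splitRhat(m, ...)
         },
         0) |> setNames(x@parameter_names)
})

#' Convergence gate
#'
#' Pipeline rule on the maximum finite split-Rhat: at most 1.05 passes, at
#' most 1.1 warns, anything larger (or non-finite) fails.
#'
#' @param rhat vector of split-Rhat values (NAs from constant parameters are
#'   ignored).
#' @param pass,warn thresholds.
#' @return list with \code{status} ("pass"/"warn"/"fail") and
#'   \code{max_rhat}.
#' @export
convergenceGate <- function(rhat, pass = 1.05, warn = 1.10) {
  r <- rhat[!is.na(rhat)]
  mx <- if (length(r)) max(r) else NA_real_
  status <- if (!is.finite(mx)) "fail"
            else if (mx <= pass) "pass"
            else if (mx <= warn) "warn" else "fail"
  list(status = status, max_rhat = mx)
}

#' @describeIn posteriorSummary pooled-chain median and central 95% credible
#'   interval per parameter, with a significance flag when the interval
#'   excludes zero (quantiles by linear interpolation of order statistics,
#'   \code{type = 7}).
#' @param prob central credible mass (default 0.95).
#' @export
setMethod("posteriorSummary", "PosteriorDraws", function(x, prob = 0.95, ...) {
  alpha <- (1 - prob) / 2
  pooled <- apply(x@draws, 3L, identity)  # (chains*kept) x params
  qs <- apply(pooled, 2L, quantile, probs = c(alpha, 0.5, 1 - alpha),
              type = .QUANTILE_TYPE, names = FALSE)
  out <- data.frame(parameter = x@parameter_names, median = qs[2, ],
                    ci_lo = qs[1, ], ci_hi = qs[3, ],
                    significant = qs[1, ] > 0 | qs[3, ] < 0,
                    row.names = NULL)
  attr(out, "quantile_type") <- .QUANTILE_TYPE
  attr(out, "prob") <- prob
  out
})

setMethod("show", "PosteriorDraws", function(object) {
  d <- dim(object@draws)
  cat(sprintf("PosteriorDraws: %d chains x %d kept x %d parameters (thin %d, warmup %d, seed %d)\n",
              d[1], d[2], d[3], object@thin, object@warmup, object@seed))
})

#' Pooled draws matrix
#' @param x a \linkS4class{PosteriorDraws}.
#' @return (chains x kept) by parameter matrix with parameter column names.
#' @export
drawsMatrix <- function(x) {
  stopifnot(is(x, "PosteriorDraws"))
  m <- apply(x@draws, 3L, identity)
  colnames(m) <- x@parameter_names
  m
}
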