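#' @import methods
#' @importFrom stats dgamma dlnorm dnorm median plogis qgamma qlogis quantile
#'   rexp rgamma rlnorm rnorm runif sd setNames var
NULL

#' Survey strata geometry
#'
#' Planar geometry of the survey strata: identifiers, centroids in km on a
#' projected plane, areas in square km, and the pairwise Euclidean distance
#' matrix that is the spatial skeleton of the correlation kernels.
#'
#' @slot ids character stratum identifiers.
#' @slot centroids numeric matrix (n x 2) of planar coordinates, km.
#' @slot areas positive numeric vector, square km.
#' @slot D symmetric distance matrix, km, consistent with the centroids.
#' @export
setClass("StrataGeometry",
  representation(ids = "character", centroids = "matrix",
                 areas = "numeric", D = "matrix"))

setValidity("StrataGeometry", function(object) {
  n <- length(object@ids)
  if (n < 3L) return("need at least 3 strata")
  if (anyDuplicated(object@ids)) return("stratum ids must be unique")
  if (!is.numeric(object@centroids) || nrow(object@centroids) != n ||
      ncol(object@centroids) != 2L)
    return("centroids must be an n x 2 numeric matrix")
  if (length(object@areas) != n || any(!is.finite(object@areas)) ||
      any(object@areas <= 0))
    return("areas must be n positive finite numbers")
  D <- object@D
  if (!is.matrix(D) || nrow(D) != n || ncol(D) != n)
    return("D must be an n x n matrix")
  ok <- tryCatch({ .checkDistance(D); TRUE }, error = function(e) e$message)
  if (!isTRUE(ok)) return(ok)
  Dc <- as.matrix(stats::dist(object@centroids))
  if (max(abs(D - Dc)) > 1e-6 * max(1, max(Dc)))
    return("D is not consistent with the centroid coordinates")
  TRUE
})

#' Stratum-by-year pond panel with design covariates
#'
#' A \linkS4class{SummarizedExperiment} with strata as rows and survey years
#' as columns.  The \code{"ponds"} assay holds the (visibility-corrected,
#' strictly positive) pond totals; each further assay holds one non-intercept
#' predictor of the linear predictor (the intercept column of ones is
#' implicit).  Row metadata carry the stratum geometry (\code{x_km},
#' \code{y_km}, \code{area_km2}); \code{metadata()} carries
#' \code{predictor_names} (assay order), \code{has_lag} and
#' \code{first_year}.  When a lag predictor is present its first-year column
#' is \code{NA} and the first year enters the model only as the lag source.
#'
#' @export
setClass("PondPanel", contains = "SummarizedExperiment")

setValidity("PondPanel", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (is.null(a) || a[1] != "ponds") return("first assay must be 'ponds'")
  ponds <- SummarizedExperiment::assay(object, "ponds")
  if (any(!is.finite(ponds)) || any(ponds <= 0))
    return("pond counts must be strictly positive and finite")
  md <- S4Vectors::metadata(object)
  pn <- md$predictor_names
  if (is.null(pn)) return("metadata()$predictor_names is missing")
  if (!identical(a[-1], pn))
    return("assays after 'ponds' must match metadata()$predictor_names")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("x_km", "y_km", "area_km2")
  if (!all(need %in% colnames(rd)))
    return("rowData must contain x_km, y_km, area_km2")
  if (any(rd$area_km2 <= 0)) return("areas must be positive")
  if (isTRUE(md$has_lag)) {
    if (!"lag" %in% pn) return("has_lag is TRUE but no 'lag' assay")
    lag <- SummarizedExperiment::assay(object, "lag")
    Y <- ncol(object)
    if (Y < 2L) return("a lagged panel needs at least 2 years")
    if (!all(is.na(lag[, 1L]))) return("lag column for the first year must be NA")
    exp_lag <- log(ponds[, -Y, drop = FALSE])
    if (max(abs(lag[, -1L, drop = FALSE] - exp_lag)) > 1e-8)
      return("lag predictor must equal log ponds of the previous year")
    modeled <- setdiff(pn, "lag")
    for (nm in modeled)
      if (any(!is.finite(SummarizedExperiment::assay(object, nm))))
        return(sprintf("predictor '%s' contains non-finite values", nm))
  } else {
    for (nm in pn)
      if (any(!is.finite(SummarizedExperiment::assay(object, nm))))
        return(sprintf("predictor '%s' contains non-finite values", nm))
  }
  TRUE
})

#' Parameters of the spatially varying coefficient model
#'
#' One point in parameter space: the global intercept \code{mu0} and mean
#' coefficients \code{mu_beta}; the stratum-level intercept deviations
#' \code{w0} and coefficient deviations \code{W} (strata x non-intercept
#' predictors); the intercept field scale \code{sigma_beta0}; per-predictor
#' field scales \code{sigma_beta}; stratum lognormal dispersions \code{tau};
#' the among-predictor correlation \code{rho}; and the two spatial decay
#' parameters \code{phi0} (intercept field) and \code{phiB} (coefficient
#' fields).
#'
#' @export
setClass("SVCParameters",
  representation(mu0 = "numeric", mu_beta = "numeric", w0 = "numeric",
                 W = "matrix", sigma_beta0 = "numeric", sigma_beta = "numeric",
                 tau = "numeric", rho = "matrix", phi0 = "numeric",
                 phiB = "numeric"))

setValidity("SVCParameters", function(object) {
  P <- length(object@mu_beta); S <- length(object@w0)
  if (length(object@mu0) != 1L) return("mu0 must be a scalar")
  if (!all(dim(object@W) == c(S, P)))
    return("W must be n_strata x n_predictors (non-intercept)")
  if (length(object@sigma_beta0) != 1L || object@sigma_beta0 < 0)
    return("sigma_beta0 must be a nonnegative scalar")
  if (length(object@sigma_beta) != P || any(object@sigma_beta < 0))
    return("sigma_beta must be nonnegative, one per predictor")
  if (length(object@tau) != S || any(object@tau <= 0))
    return("tau must be positive, one per stratum")
  ok <- tryCatch({ .checkCorrelation(object@rho); TRUE },
                 error = function(e) e$message)
  if (!isTRUE(ok)) return(ok)
  if (nrow(object@rho) != P) return("rho must be P x P")
  if (object@phi0 <= 0 || object@phiB <= 0) return("phi must be positive")
  TRUE
})

#' Uniform prior bounds for the spatial decay parameters
#' @export
setClass("PhiBounds", representation(lower = "numeric", upper = "numeric"))

setValidity("PhiBounds", function(object) {
  if (length(object@lower) != 1L || length(object@upper) != 1L)
    return("bounds must be scalars")
  if (!(object@lower > 0 && object@lower < object@upper))
    return("need 0 < lower < upper")
  TRUE
})

#' Posterior draws with chain structure
#'
#' @slot draws 3-d array: chain x iteration x parameter.
#' @slot parameter_names character labels of the third dimension.
#' @slot seed integer seed of the run.
#' @slot warmup,kept,thin integers of the chain protocol (sweeps discarded,
#'   draws kept per chain, sweeps between kept draws).
#' @slot diagnostics list: per-chain block acceptance rates, phi bounds,
#'   sampler settings.
#' @export
setClass("PosteriorDraws",
  representation(draws = "array", parameter_names = "character",
                 seed = "integer", warmup = "integer", kept = "integer",
                 thin = "integer", diagnostics = "list"))

setValidity("PosteriorDraws", function(object) {
  d <- dim(object@draws)
  if (length(d) != 3L) return("draws must be chain x iteration x parameter")
  if (d[3] != length(object@parameter_names))
    return("parameter_names must match dim(draws)[3]")
  if (any(!is.finite(object@draws))) return("draws contain non-finite values")
  TRUE
})

#' Posterior summaries of derived ecological quantities
#'
#' @slot effective_range data.frame (quantity, median, ci_lo, ci_hi) for the
#'   intercept and coefficient spatial ranges, km.
#' @slot variance_proportions data.frame (stratum, predictor, median, ci_lo,
#'   ci_hi) of the per-stratum variance decomposition, including the
#'   \code{"residual"} fraction.
#' @slot density_cv data.frame (stratum, quantity, median, ci_lo, ci_hi) of
#'   mean pond density (per square km) and the coefficient of variation.
#' @slot meta list (number of draws, quantile rule, cv form).
#' @export
setClass("DerivedSummary",
  representation(effective_range = "data.frame",
                 variance_proportions = "data.frame",
                 density_cv = "data.frame", meta = "list"))
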