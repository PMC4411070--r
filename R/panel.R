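## The stratum x year design panel: constructor and accessors.

#' Construct a PondPanel
#'
#' Assembles the pond counts and the non-intercept predictor matrices into
#' the panel object consumed by the model.  Predictors are stratum x year
#' matrices; a predictor named \code{"lag"} must equal the log of the
#' previous year's pond count (its first-year column is \code{NA} and that
#' year enters the likelihood only as the lag source).
#'
#' @param ponds stratum x year matrix of positive pond totals.
#' @param predictors named list of stratum x year predictor matrices, in
#'   model order.
#' @param geometry a \linkS4class{StrataGeometry} matching the rows.
#' @param years integer survey years labelling the columns.
#' @return a \linkS4class{PondPanel}.
#' @export
PondPanel <- function(ponds, predictors, geometry, years = NULL) {
  ponds <- as.matrix(ponds)
  S <- nrow(ponds); Y <- ncol(ponds)
  if (length(strataIds(geometry)) != S)
    stop("geometry does not match the number of panel rows")
  if (is.null(years)) {
    years <- suppressWarnings(as.integer(colnames(ponds)))
    if (any(is.na(years))) years <- seq_len(Y)
  }
  if (length(years) != Y) stop("years must label every panel column")
  if (is.null(names(predictors)) || any(names(predictors) == ""))
    stop("predictors must be a fully named list")
  ids <- strataIds(geometry)
  dn <- list(ids, as.character(years))
  dimnames(ponds) <- dn
  assays <- c(list(ponds = ponds),
              lapply(predictors, function(m) {
                m <- as.matrix(m)
                if (!all(dim(m) == c(S, Y)))
                  stop("every predictor must be a stratum x year matrix")
                dimnames(m) <- dn
                m
              }))
  rd <- S4Vectors::DataFrame(x_km = centroids(geometry)[, 1],
                             y_km = centroids(geometry)[, 2],
                             area_km2 = strataAreas(geometry),
                             row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, rowData = rd,
    colData = S4Vectors::DataFrame(year = years, row.names = as.character(years)),
    metadata = list(predictor_names = names(predictors),
                    has_lag = "lag" %in% names(predictors),
                    first_year = years[1L]))
  new("PondPanel", se)
}

#' @aliases pondCounts,PondPanel-method
#' @export
setMethod("pondCounts", "PondPanel", function(x)
  SummarizedExperiment::assay(x, "ponds"))

#' @aliases predictorNames,PondPanel-method
#' @export
setMethod("predictorNames", "PondPanel", function(x)
  S4Vectors::metadata(x)$predictor_names)

#' @aliases offsetLogArea,PondPanel-method
#' @export
setMethod("offsetLogArea", "PondPanel", function(x) {
  a <- SummarizedExperiment::rowData(x)$area_km2
  structure(log(a), names = rownames(x))
})

#' @aliases strataGeometry,PondPanel-method
#' @export
setMethod("strataGeometry", "PondPanel", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  StrataGeometry(ids = rownames(x),
                 centroids = cbind(x_km = rd$x_km, y_km = rd$y_km),
                 areas = rd$area_km2)
})

#' @aliases modeledYears,PondPanel-method
#' @export
setMethod("modeledYears", "PondPanel", function(x) {
  if (isTRUE(S4Vectors::metadata(x)$has_lag)) seq_len(ncol(x))[-1L]
  else seq_len(ncol(x))
})

#' @aliases designArray,PondPanel-method
#' @param x a PondPanel.
#' @return \code{designArray} returns the stratum x year x predictor array
#'   with the leading all-ones intercept slice.
#' @export
setMethod("designArray", "PondPanel", function(x) {
  pn <- predictorNames(x)
  S <- nrow(x); Y <- ncol(x)
  X <- array(NA_real_, dim = c(S, Y, 1L + length(pn)),
             dimnames = list(rownames(x), colnames(x), c("intercept", pn)))
  X[, , 1L] <- 1
  for (k in seq_along(pn))
    X[, , k + 1L] <- SummarizedExperiment::assay(x, pn[k])
  X
})

setMethod("show", "PondPanel", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("PondPanel: %d strata x %d years (%s-%s)%s\n",
              nrow(object), ncol(object), colnames(object)[1],
              colnames(object)[ncol(object)],
              if (isTRUE(md$has_lag)) ", first year = lag source" else ""))
  cat("  predictors:", paste(md$predictor_names, collapse = ", "), "\n")
})
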