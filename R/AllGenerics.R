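#' @rdname StrataGeometry-class
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname StrataGeometry-class
#' @export
setGeneric("strataIds", function(x) standardGeneric("strataIds"))

#' @rdname StrataGeometry-class
#' @export
setGeneric("strataAreas", function(x) standardGeneric("strataAreas"))

#' @rdname StrataGeometry-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname PondPanel-class
#' @export
setGeneric("pondCounts", function(x) standardGeneric("pondCounts"))

#' @rdname PondPanel-class
#' @export
setGeneric("designArray", function(x) standardGeneric("designArray"))

#' @rdname PondPanel-class
#' @export
setGeneric("offsetLogArea", function(x) standardGeneric("offsetLogArea"))

#' @rdname PondPanel-class
#' @export
setGeneric("predictorNames", function(x) standardGeneric("predictorNames"))

#' @rdname PondPanel-class
#' @export
setGeneric("strataGeometry", function(x) standardGeneric("strataGeometry"))

#' @rdname PondPanel-class
#' @export
setGeneric("modeledYears", function(x) standardGeneric("modeledYears"))

#' Pooled-chain posterior summaries
#' @param x a \linkS4class{PosteriorDraws} object.
#' @param ... passed to methods.
#' @export
setGeneric("posteriorSummary", function(x, ...) standardGeneric("posteriorSummary"))

#' Split potential scale reduction factor
#' @param x a \linkS4class{PosteriorDraws} object or a chain x iteration
#'   matrix for a single parameter.
#' @param ... passed to methods.
#' @export
setGeneric("splitRhat", function(x, ...) standardGeneric("splitRhat"))
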