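## Strata geometry: construction, accessors, synthetic lattice generator.

#' Construct a StrataGeometry
#'
#' @param ids character stratum identifiers.
#' @param centroids n x 2 matrix of planar coordinates (km).
#' @param areas positive stratum areas (square km).
#' @return a \linkS4class{StrataGeometry}; the pairwise Euclidean distance
#'   matrix is computed from the centroids.
#' @export
StrataGeometry <- function(ids, centroids, areas) {
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  D <- as.matrix(stats::dist(centroids))
  dimnames(D) <- list(ids, ids)
  rownames(centroids) <- ids
  new("StrataGeometry", ids = as.character(ids), centroids = centroids,
      areas = as.numeric(areas), D = D)
}

#' @rdname StrataGeometry-class
#' @param x a StrataGeometry.
#' @aliases distanceMatrix,StrataGeometry-method
#' @export
setMethod("distanceMatrix", "StrataGeometry", function(x) x@D)

#' @aliases strataIds,StrataGeometry-method
#' @export
setMethod("strataIds", "StrataGeometry", function(x) x@ids)

#' @aliases strataAreas,StrataGeometry-method
#' @export
setMethod("strataAreas", "StrataGeometry", function(x) {
  structure(x@areas, names = x@ids)
})

#' @aliases centroids,StrataGeometry-method
#' @export
setMethod("centroids", "StrataGeometry", function(x) x@centroids)

setMethod("show", "StrataGeometry", function(object) {
  D <- object@D
  off <- D[upper.tri(D)]
  cat(sprintf("StrataGeometry: %d strata\n", length(object@ids)))
  cat(sprintf("  areas (km^2): median %.0f, range [%.0f, %.0f]\n",
              median(object@areas), min(object@areas), max(object@areas)))
  cat(sprintf("  inter-stratum distance (km): min %.0f, max %.0f\n",
              min(off), max(off)))
})

#' Nearest-neighbour distances among strata
#' @param geometry a \linkS4class{StrataGeometry}.
#' @return numeric vector, km, one per stratum.
#' @export
nearestNeighbourDistances <- function(geometry) {
  D <- distanceMatrix(geometry)
  diag(D) <- Inf
  apply(D, 1L, min)
}

#' Synthetic survey lattice
#'
#' Generates an irregular lattice of stratum centroids emulating the layout
#' of a stratified aerial survey: a near-square grid covering the extent,
#' jittered so that no two strata coincide, with lognormal stratum areas.
#' Deterministic given the seed.
#'
#' @param n_strata number of strata (at least 3).
#' @param extent_km side of the square survey extent, km.
#' @param seed integer seed.
#' @param area_mean_km2 mean stratum area.
#' @param area_sdlog lognormal log-scale sd of the areas.
#' @return a \linkS4class{StrataGeometry}.
#' @export
makeGeometry <- function(n_strata, extent_km = 1500, seed = 1L,
                         area_mean_km2 = 17000, area_sdlog = 0.4) {
  if (n_strata < 3L) stop("n_strata must be at least 3")
  if (extent_km <= 0) stop("extent_km must be positive")
  set.seed(as.integer(seed))
  ncol_g <- ceiling(sqrt(n_strata))
  nrow_g <- ceiling(n_strata / ncol_g)
  cell <- extent_km / max(ncol_g, nrow_g)
  g <- expand.grid(col = seq_len(ncol_g), row = seq_len(nrow_g))[seq_len(n_strata), ]
  x <- (g$col - 0.5) * cell + runif(n_strata, -0.35, 0.35) * cell
  y <- (g$row - 0.5) * cell + runif(n_strata, -0.35, 0.35) * cell
  areas <- rlnorm(n_strata,
                  meanlog = log(area_mean_km2) - area_sdlog^2 / 2,
                  sdlog = area_sdlog)
  StrataGeometry(ids = sprintf("s%02d", seq_len(n_strata)),
                 centroids = cbind(x_km = x, y_km = y), areas = areas)
}
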