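## Plain-CSV input/output and the JSON run manifest.
##
## Schemas: ponds (stratum, year, ponds); geometry (stratum, x_km, y_km,
## area_km2); monthly climate (stratum, year, month, precip_mm, tmax_c);
## summaries (parameter, median, ci_lo, ci_hi[, significant]); variance
## proportions (stratum, predictor, proportion_median, ci_lo, ci_hi).

#' Read a pond count table
#'
#' Long CSV (stratum, year, ponds) into a dense stratum x year matrix, with
#' named validation errors for duplicates, missing cells, and nonpositive
#' counts.
#'
#' @param path CSV file path.
#' @return stratum x year matrix with year column names.
#' @export
readPondTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "year", "ponds")
  if (!all(need %in% names(d)))
    stop("pond table must have columns stratum, year, ponds")
  if (!is.numeric(d$ponds) || any(!is.finite(d$ponds)))
    stop("ponds must be finite numbers")
  dup <- duplicated(d[c("stratum", "year")])
  if (any(dup))
    stop(sprintf("duplicated pond record for stratum %s, year %s",
                 d$stratum[dup][1], d$year[dup][1]))
  if (any(d$ponds <= 0)) {
    i <- which(d$ponds <= 0)[1]
    stop(sprintf("nonpositive pond count for stratum %s, year %s",
                 d$stratum[i], d$year[i]))
  }
  strata <- sort(unique(as.character(d$stratum)))
  years <- sort(unique(d$year))
  m <- matrix(NA_real_, length(strata), length(years),
              dimnames = list(strata, as.character(years)))
  m[cbind(match(as.character(d$stratum), strata), match(d$year, years))] <- d$ponds
  if (anyNA(m)) {
    i <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing pond count for stratum %s, year %s",
                 strata[i[1]], years[i[2]]))
  }
  m
}

#' Write a pond count table
#' @param ponds stratum x year matrix.
#' @param path output CSV path.
#' @export
writePondTable <- function(ponds, path) {
  d <- expand.grid(stratum = rownames(ponds),
                   year = as.integer(colnames(ponds)),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$ponds <- as.vector(ponds)
  utils::write.csv(d[order(d$stratum, d$year), ], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read stratum geometry
#' @param path CSV with columns stratum, x_km, y_km, area_km2.
#' @return a \linkS4class{StrataGeometry}.
#' @export
readGeometryTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "x_km", "y_km", "area_km2")
  if (!all(need %in% names(d)))
    stop("geometry table must have columns stratum, x_km, y_km, area_km2")
  d <- d[order(d$stratum), ]
  StrataGeometry(ids = as.character(d$stratum),
                 centroids = cbind(x_km = d$x_km, y_km = d$y_km),
                 areas = d$area_km2)
}

#' @rdname readGeometryTable
#' @param geometry a \linkS4class{StrataGeometry}.
#' @export
writeGeometryTable <- function(geometry, path) {
  xy <- centroids(geometry)
  utils::write.csv(data.frame(stratum = strataIds(geometry),
                              x_km = xy[, 1], y_km = xy[, 2],
                              area_km2 = unname(strataAreas(geometry))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monthly climate table
#' @param path CSV with columns stratum, year, month, precip_mm, tmax_c.
#' @return validated data.frame.
#' @export
readClimateTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "year", "month", "precip_mm", "tmax_c")
  if (!all(need %in% names(d)))
    stop("climate table must have columns stratum, year, month, precip_mm, tmax_c")
  if (any(d$precip_mm < 0)) stop("monthly precipitation must be nonnegative")
  if (any(!d$month %in% 1:12)) stop("month must be 1-12")
  if (anyDuplicated(d[c("stratum", "year", "month")]))
    stop("duplicate stratum-year-month climate records")
  d
}

#' Expand a seasonal climate panel to a monthly table
#'
#' Splits each seasonal precipitation total uniformly over its three months
#' and repeats the seasonal mean temperature, labelling calendar months so
#' that the seasonal windows of [seasonalAggregate()] reproduce the panel
#' exactly.  This is the CSV surface of the synthetic climate generator.
#'
#' @param climate a \linkS4class{ClimatePanel}.
#' @param years survey years labelling the panel's year dimension.
#' @return monthly climate data.frame.
#' @export
climateToMonthly <- function(climate, years) {
  d3 <- dim(climate@precip)
  S <- d3[1]; Y <- d3[2]
  if (length(years) != Y) stop("years must label every climate year")
  ids <- dimnames(climate@precip)[[1]]
  rows <- vector("list", Y * 4L)
  k <- 0L
  for (t in seq_len(Y)) {
    for (season in names(.SEASON_MONTHS)) {
      months <- .SEASON_MONTHS[[season]]
      cal_years <- switch(season,
        summer = , fall = rep(years[t] - 1L, 3L),
        winter = c(years[t] - 1L, years[t], years[t]),
        spring = rep(years[t], 3L))
      si <- match(season, climate@seasons)
      for (j in 1:3) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          stratum = ids, year = cal_years[j], month = months[j],
          precip_mm = climate@precip[, t, si] / 3,
          tmax_c = climate@tmax[, t, si])
      }
    }
  }
  d <- do.call(rbind, rows)
  ## overlapping windows (summer of one survey year is not used by the
  ## next): keep the first occurrence of each stratum-year-month
  d <- d[!duplicated(d[c("stratum", "year", "month")]), ]
  rownames(d) <- NULL
  d
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a pipeline stage bit-exactly:
#' seed, settings, input hashes and diagnostics.
#'
#' @param manifest named list.
#' @param path output path.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

## stable hash of a settings list for manifests (no external digest dep);
## output locations do not affect reproducibility and are excluded
.configHash <- function(x) {
  x <- x[setdiff(names(x), c("out", "help"))]
  s <- paste(utils::capture.output(utils::str(x, digits.d = 15)), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
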