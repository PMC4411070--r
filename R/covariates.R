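## Covariate construction: monthly climate -> seasonal windows -> the model
## design panel.

.SEASON_MONTHS <- list(summer = 6:8, fall = 9:11, winter = c(12, 1, 2),
                       spring = 3:5)

#' Aggregate monthly climate into the four pre-survey seasons
#'
#' For a late-May survey in year \code{t} the relevant seasons are: summer =
#' Jun-Aug of \code{t-1}, fall = Sep-Nov of \code{t-1}, winter = Dec of
#' \code{t-1} plus Jan-Feb of \code{t}, spring = Mar-May of \code{t}.
#' Precipitation is summed over the three months, temperature averaged
#' (unweighted).
#'
#' @param monthly data.frame with columns \code{stratum}, \code{year}
#'   (calendar), \code{month} (1-12), \code{precip_mm}, \code{tmax_c}; one
#'   row per stratum-year-month.
#' @param survey_year the survey year \code{t}.
#' @return data.frame with one row per stratum and columns
#'   \code{precip_<season>} (mm totals) and \code{tmax_<season>} (mean
#'   degrees C).
#' @export
seasonalAggregate <- function(monthly, survey_year) {
  need <- c("stratum", "year", "month", "precip_mm", "tmax_c")
  if (!all(need %in% names(monthly)))
    stop("monthly table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(monthly[c("stratum", "year", "month")]))
    stop("duplicate stratum-year-month records in the monthly table")
  strata <- sort(unique(as.character(monthly$stratum)))
  key <- paste(monthly$stratum, monthly$year, monthly$month, sep = "\r")
  out <- data.frame(stratum = strata)
  for (season in names(.SEASON_MONTHS)) {
    months <- .SEASON_MONTHS[[season]]
    years <- if (season %in% c("summer", "fall")) rep(survey_year - 1L, 3L)
             else if (season == "winter") c(survey_year - 1L, survey_year, survey_year)
             else rep(survey_year, 3L)
    pr <- tm <- matrix(NA_real_, length(strata), 3L)
    for (j in 1:3) {
      i <- match(paste(strata, years[j], months[j], sep = "\r"), key)
      if (anyNA(i)) {
        miss <- strata[which(is.na(i))[1]]
        stop(sprintf("missing monthly climate: stratum %s, year %d, month %d",
                     miss, years[j], months[j]))
      }
      pr[, j] <- monthly$precip_mm[i]
      tm[, j] <- monthly$tmax_c[i]
    }
    out[[paste0("precip_", season)]] <- rowSums(pr)
    out[[paste0("tmax_", season)]] <- rowMeans(tm)
  }
  out
}

#' Assemble the model design panel
#'
#' Builds the \linkS4class{PondPanel} with the canonical predictor order:
#' intercept (implicit), log of the previous year's pond total, linear time
#' (survey year minus first year), four seasonal log-precipitation totals
#' and four seasonal mean temperatures; the offset is the log stratum area.
#' The first panel year is present only as the lag source.  Zero or negative
#' ponds or seasonal precipitation are domain errors: they indicate upstream
#' data failure and are never silently adjusted.
#'
#' @param ponds stratum x year matrix of positive pond totals with year
#'   column names, or a long data.frame as read by [readPondTable()].
#' @param climate either a \linkS4class{ClimatePanel} whose year dimension
#'   matches the pond years, or a monthly climate data.frame (see
#'   [seasonalAggregate()]) covering every survey year.
#' @param geometry a \linkS4class{StrataGeometry} whose ids match the pond
#'   rows.
#' @return a \linkS4class{PondPanel}.
#' @export
buildDesign <- function(ponds, climate, geometry) {
  ponds <- as.matrix(ponds)
  if (any(!is.finite(ponds)) || any(ponds <= 0))
    stop("pond totals must be strictly positive; zero counts indicate upstream data failure")
  S <- nrow(ponds); Y <- ncol(ponds)
  if (Y < 2L) stop("need at least two years (the first is the lag source)")
  ids <- strataIds(geometry)
  if (S != length(ids)) stop("ponds rows do not match the geometry")
  if (!is.null(rownames(ponds)) && !identical(rownames(ponds), ids))
    stop("ponds row names do not match the geometry stratum ids")
  years <- suppressWarnings(as.integer(colnames(ponds)))
  if (anyNA(years)) stop("pond columns must be named by survey year")

  if (is(climate, "ClimatePanel")) {
    if (dim(climate@precip)[2] != Y)
      stop("climate years do not match the pond panel")
    clim <- .climatePredictors(climate)
  } else {
    seasons <- names(.SEASON_MONTHS)
    clim <- list()
    for (nm in c(paste0("precip_", seasons), paste0("tmax_", seasons)))
      clim[[nm]] <- matrix(NA_real_, S, Y)
    for (t in seq_len(Y)) {
      agg <- seasonalAggregate(climate, years[t])
      i <- match(ids, agg$stratum)
      if (anyNA(i)) stop("monthly climate is missing strata present in the pond table")
      for (season in seasons) {
        clim[[paste0("precip_", season)]][, t] <- agg[[paste0("precip_", season)]][i]
        clim[[paste0("tmax_", season)]][, t] <- agg[[paste0("tmax_", season)]][i]
      }
    }
    for (season in seasons) {
      if (any(clim[[paste0("precip_", season)]] <= 0))
        stop("zero seasonal precipitation total: invalid upstream climate data")
      clim[[paste0("precip_", season)]] <- log(clim[[paste0("precip_", season)]])
    }
  }
  predictors <- c(
    list(lag = cbind(NA_real_, log(ponds[, -Y, drop = FALSE])),
         time = matrix(rep(years - years[1L], each = S), S, Y)),
    clim)
  PondPanel(ponds, predictors, geometry, years = years)
}
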