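# Inverse-distance-weighted exposure assignment.
#
# Daily concentration at a residence = sum(value_k / d_k) / sum(1 / d_k) over
# monitors with a reading that day within the search radius, d_k the haversine
# distance in km. A monitor coinciding with the residence (d = 0) returns its
# value directly, the d -> 0 limit of the weighted mean. Window estimates
# average the daily values over the 91 days ending the day before the anchor.

EARTH_RADIUS_KM <- 6371.0088

haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Daily inverse-distance-weighted concentration at a point
#'
#' @param point numeric `c(lat, lon)` in decimal degrees (WGS84).
#' @param date a `Date` (or coercible string).
#' @param pollutant `"pm25"` or `"pm10"`.
#' @param monitors data.frame with columns `monitor_id`, `lat`, `lon`,
#'   `date`, `pollutant`, `value`.
#' @param radius_km search radius; monitors at distance <= `radius_km`
#'   contribute (default 60).
#' @return the weighted concentration, or `NA` with attribute
#'   `reason = "no coverage"` when no in-radius monitor reported that day.
#' @examples
#' m <- data.frame(monitor_id = "a", lat = 40, lon = -83,
#'                 date = as.Date("1999-01-01"), pollutant = "pm10", value = 20)
#' daily_idw(c(40.1, -83), as.Date("1999-01-01"), "pm10", m)
#' @export
daily_idw <- function(point, date, pollutant, monitors, radius_km = 60) {
  date <- as.Date(date)
  m <- monitors[monitors$pollutant == pollutant & monitors$date == date, ,
                drop = FALSE]
  if (nrow(m) == 0) return(no_coverage())
  d <- haversine_km(point[1], point[2], m$lat, m$lon)
  keep <- d <= radius_km
  if (!any(keep)) return(no_coverage())
  d <- d[keep]; v <- m$value[keep]
  if (any(d == 0)) return(mean(v[d == 0]))
  sum(v / d) / sum(1 / d)
}

no_coverage <- function() structure(NA_real_, reason = "no coverage")

#' Windowed average exposure before an anchor date
#'
#' Averages [daily_idw()] over the `window_days` days ending the day before
#' `anchor_date` (half-open; the anchor itself excluded). Days without
#' monitor coverage are omitted from the mean; the estimate is marked missing
#' when the covered fraction falls below `min_coverage`.
#'
#' @inheritParams daily_idw
#' @param anchor_date the anchor (e.g. birth date).
#' @param window_days window length (default 91 days, i.e. three months).
#' @param min_coverage minimum fraction of covered days (default 0.75).
#' @return a one-row data.frame: `value`, `n_monitor_days`,
#'   `coverage_fraction`, `reason` (`NA` when estimated).
#' @export
window_average <- function(point, anchor_date, pollutant, monitors,
                           radius_km = 60, window_days = 91,
                           min_coverage = 0.75) {
  anchor_date <- as.Date(anchor_date)
  days <- seq(anchor_date - window_days, anchor_date - 1, by = "day")
  m <- monitors[monitors$pollutant == pollutant & monitors$date %in% days, ,
                drop = FALSE]
  vals <- vapply(days, function(d) as.numeric(daily_idw(point, d, pollutant, m,
                                                        radius_km)), 0)
  covered <- sum(!is.na(vals))
  cf <- covered / window_days
  if (covered == 0)
    return(data.frame(value = NA_real_, n_monitor_days = 0L,
                      coverage_fraction = 0, reason = "no coverage",
                      stringsAsFactors = FALSE))
  if (cf < min_coverage)
    return(data.frame(value = NA_real_, n_monitor_days = covered,
                      coverage_fraction = cf, reason = "insufficient coverage",
                      stringsAsFactors = FALSE))
  data.frame(value = mean(vals, na.rm = TRUE), n_monitor_days = covered,
             coverage_fraction = cf, reason = NA_character_,
             stringsAsFactors = FALSE)
}

#' Windowed IDW exposure for every residence
#'
#' @param residences data.frame with `participant_id`, `lat`, `lon` and one
#'   date column per anchor (`birth_date`, `age1_date`, `age3_date`).
#' @param monitors monitor series as in [daily_idw()].
#' @param pollutant `"pm25"` or `"pm10"`.
#' @param anchor `"birth"`, `"age1"` or `"age3"`.
#' @inheritParams window_average
#' @return data.frame of exposure estimates, one row per participant:
#'   `participant_id`, `pollutant`, `anchor`, `value`, `n_monitor_days`,
#'   `coverage_fraction`, `reason`.
#' @export
compute_exposures <- function(residences, monitors, pollutant,
                              anchor = c("birth", "age1", "age3"),
                              radius_km = 60, window_days = 91,
                              min_coverage = 0.75) {
  anchor <- match.arg(anchor)
  dcol <- paste0(anchor, "_date")
  if (!dcol %in% names(residences)) stop_ms("residences lack column %s", dcol)
  monitors$date <- as.Date(monitors$date)
  mp <- monitors[monitors$pollutant == pollutant, , drop = FALSE]
  # monitor locations are static: restrict each residence's series to
  # in-radius monitors once, instead of rescanning the full table per day
  loc <- unique(mp[, c("monitor_id", "lat", "lon")])
  by_id <- split(seq_len(nrow(mp)), mp$monitor_id)
  rows <- lapply(seq_len(nrow(residences)), function(i) {
    r <- residences[i, ]
    d <- haversine_km(r$lat, r$lon, loc$lat, loc$lon)
    ids <- loc$monitor_id[d <= radius_km]
    sub <- mp[unlist(by_id[ids], use.names = FALSE), , drop = FALSE]
    est <- window_average(c(r$lat, r$lon), as.Date(r[[dcol]]), pollutant,
                          sub, radius_km, window_days, min_coverage)
    cbind(data.frame(participant_id = r$participant_id, pollutant = pollutant,
                     anchor = anchor, stringsAsFactors = FALSE), est)
  })
  do.call(rbind, rows)
}
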