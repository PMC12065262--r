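#' Astronomical day length
#'
#' Day length from the standard sunrise equation: solar declination from
#' the Spencer Fourier series in day-of-year, hour angle
#' `H = acos(-tan(lat) tan(decl))`, day length `2H` expressed in hours.
#' Polar night and polar day return 0 and 24 h rather than erroring.
#'
#' @param lat latitude, degrees (|lat| <= 90); vectorized
#' @param date `Date` vector (recycled against `lat`)
#' @return day length in hours
#' @examples
#' day_length_hours(0, as.Date("2005-03-21"))   # ~12 h
#' @export
day_length_hours <- function(lat, date) {
  if (any(abs(lat) > 90)) stop("|lat| must be <= 90", call. = FALSE)
  n <- as.POSIXlt(date)$yday + 1
  g <- 2 * pi * (n - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  cos_h <- clamp(-tan(lat * pi / 180) * tan(decl), -1, 1)
  2 * acos(cos_h) * 180 / pi / 15
}

#' Moon illuminated fraction
#'
#' Percentage of the lunar disc illuminated, from a simple synodic-cycle
#' approximation: phase age measured from the new moon of 2000-01-06 with a
#' 29.530589-day period, illumination `100 * (1 - cos(2*pi*age/period)) / 2`.
#' Adequate for a smooth 0-100% covariate with the correct ~29.53-day
#' periodicity; not an ephemeris.
#'
#' @param date `Date` vector
#' @return percent illuminated in [0, 100]
#' @export
moon_fraction <- function(date) {
  synodic <- 29.530588853
  age <- as.numeric(as.Date(date) - as.Date("2000-01-06")) %% synodic
  100 * (1 - cos(2 * pi * age / synodic)) / 2
}

# local solar hour in [0, 24) from UTC time and longitude
local_solar_hour <- function(time_utc, lon) {
  lt <- as.POSIXlt(time_utc, tz = "UTC")
  (lt$hour + lt$min / 60 + lt$sec / 3600 + lon / 15) %% 24
}

# local solar date: UTC timestamp shifted by the longitude-derived offset
local_solar_date <- function(time_utc, lon) {
  as.Date(as.POSIXct(time_utc, tz = "UTC") + lon / 15 * 3600, tz = "UTC")
}

# assign each minute sample of a tag record to a deployment day by
# longitude-derived local solar date (two passes: a provisional UTC-date
# assignment supplies the per-minute longitude)
minute_day_index <- function(tag) {
  d <- tag$daily
  nd <- nrow(d)
  ts <- tag$minute$timestamp
  prov <- clamp(findInterval(as.Date(ts, tz = "UTC"), d$date), 1, nd)
  ldate <- local_solar_date(ts, d$lon[prov])
  clamp(as.integer(ldate - d$date[1]) + 1L, 1, nd)
}
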