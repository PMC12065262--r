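#' Great-circle distance
#'
#' Haversine distance on a sphere (default radius 6371 km). Vectorized over
#' point pairs.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees
#' @param radius_km sphere radius, km
#' @return distance in km
#' @examples
#' great_circle_km(0, 0, 0, 1)   # ~111.19 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  if (any(abs(c(lat1, lat2)) > 90))
    stop("|lat| must be <= 90", call. = FALSE)
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Smooth a daily distance series
#'
#' Centered 7-day moving mean (the geolocation-error smoother for daily
#' track distances); edges use the mean of the available window, so the
#' output length equals the input length. Series shorter than the window
#' pass through with a warning.
#'
#' @param x numeric series
#' @param window window width, days
#' @return smoothed series, same length as `x`
#' @export
smooth_distances <- function(x, window = 7) {
  if (length(x) < window) {
    warning("series shorter than the smoothing window; returned unchanged")
    return(x)
  }
  as.numeric(zoo::rollapply(x, width = window, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Daily vertical distance from a depth trace
#'
#' Half the total distance traveled in the vertical plane (descents are
#' assumed nearly free): `0.5 * sum(|depth steps|)`, in km. Steps across
#' sampling gaps longer than `gap_min` minutes are excluded.
#'
#' @param depth_m depth samples for one day, m
#' @param timestamps optional POSIXct sample times (for gap exclusion)
#' @param gap_min gap threshold, minutes
#' @return vertical distance, km
#' @examples
#' vertical_km(c(0, 100, 0))   # 0.1 km
#' @export
vertical_km <- function(depth_m, timestamps = NULL, gap_min = 2) {
  if (length(depth_m) < 2) return(0)
  steps <- abs(diff(depth_m))
  if (!is.null(timestamps)) {
    dt <- diff(as.numeric(timestamps)) / 60
    steps <- steps[dt <= gap_min + 1e-9]
  }
  0.5 * sum(steps) / 1000
}

#' Convert a daily 3-D distance to swimming speed
#'
#' Total daily distance (horizontal + vertical path length, km) over 86,400
#' seconds, expressed in body lengths per second.
#'
#' @param horizontal_km,vertical_km_day daily distances, km
#' @param length_cm fork length, cm (> 0)
#' @return speed in BL s-1
#' @examples
#' speed_bls(86.4, 0, 100)   # 1 BL/s
#' @export
speed_bls <- function(horizontal_km, vertical_km_day, length_cm) {
  if (any(length_cm <= 0)) stop("length must be > 0", call. = FALSE)
  (horizontal_km + vertical_km_day) * 1000 / 86400 / (length_cm / 100)
}

#' Daily kinematics of a tagged fish
#'
#' Per-day horizontal distance between consecutive daily positions
#' (7-day-smoothed), vertical distance from the 1-min depth trace, swimming
#' speed, interpolated length and allometric weight, mean tag-recorded
#' ambient temperature across all depths, and mean depth.
#'
#' @param tag a `tag_record`
#' @param const an [energetics_constants()]
#' @return data.frame, one row per deployment day
#' @export
track_kinematics <- function(tag, const = energetics_constants()) {
  d <- tag$daily
  n <- nrow(d)
  raw_km <- c(0, great_circle_km(d$lat[-n], d$lon[-n], d$lat[-1], d$lon[-1]))
  horiz <- smooth_distances(raw_km)
  m <- tag$minute
  day_idx <- minute_day_index(tag)
  vert <- vapply(seq_len(n), function(i) {
    sel <- day_idx == i
    vertical_km(m$depth_m[sel], m$timestamp[sel])
  }, 0)
  ambient <- as.numeric(tapply(m$ambient_temp_C, day_idx, mean))
  mean_depth <- as.numeric(tapply(m$depth_m, day_idx, mean))
  weight <- length_to_weight(d$length_cm, const)
  data.frame(day = d$day, date = d$date, lat = d$lat, lon = d$lon,
             horizontal_km = horiz, vertical_km = vert,
             total_km = horiz + vert,
             speed_bls = speed_bls(horiz, vert, d$length_cm),
             length_cm = d$length_cm, weight_kg = weight,
             ambient_temp_C = ambient, mean_depth_m = mean_depth)
}

#' Daily energetic gains, costs, and balances along a tag track
#'
#' Observed-track mode of the chain: ambient temperature is the tag's mean
#' daily external temperature across all depths; movement cost comes from
#' the cost model at the observed 3-D swimming speed, converted to kJ with
#' the interpolated daily weight over 24 h; ingested energy comes from the
#' ingestion model applied to the observed daily Heat Increment of Feeding
#' (extracted from the body-temperature trace unless supplied); the balance
#' is ingested minus fixed losses minus movement cost.
#'
#' @param tag a `tag_record`
#' @param models model list from [fit_energetics_models()] (only `cost` and
#'   `ingestion` are used)
#' @param const an [energetics_constants()]
#' @param daily_hif optional data.frame from [compute_daily_hif()]
#' @return data.frame, one row per day, including `ingested_kj`,
#'   `movement_cost_kj`, `balance_kj`
#' @export
track_daily_energetics <- function(tag, models,
                                   const = energetics_constants(),
                                   daily_hif = NULL) {
  kin <- track_kinematics(tag, const)
  if (is.null(daily_hif))
    daily_hif <- compute_daily_hif(tag, estimate_baseline(tag))
  kin$hif <- daily_hif$hif[match(kin$date, daily_hif$date)]
  kin$hif[is.na(kin$hif)] <- 0
  mo2 <- predict(models$cost,
                 data.frame(temperature = kin$ambient_temp_C,
                            speed = kin$speed_bls))
  kin$movement_cost_kj <- mo2_to_kj(pmax(mo2, 0), kin$weight_kg, 24, const)
  kin$ingested_kj <- predict_ingestion(models$ingestion, kin$hif,
                                       kin$ambient_temp_C,
                                       const$pct_finfish)
  kin$balance_kj <- daily_balance(kin$ingested_kj, kin$movement_cost_kj,
                                  const)
  kin
}

#' Re-experience a track under two environmental periods
#'
#' Replays an observed track under historical and future environmental
#' fields: per day and period, ambient temperature is the linear SST/T200
#' profile at the tag's mean daily depth, the Heat Increment of Feeding
#' comes from the foraging model at the period's mesozooplankton, ingestion
#' and cost follow the chain with the *observed* daily swimming speeds, and
#' the change is future minus historical. 7-day running means are appended.
#'
#' @param tag a `tag_record`
#' @param env_hist,env_fut `env_field_set`s on a common grid
#' @param models model list from [fit_energetics_models()]
#' @param const an [energetics_constants()]
#' @return data.frame with per-day balances under both periods,
#'   `delta_balance_kj`, and 7-day running means (`*_7d`)
#' @export
reexperience_track <- function(tag, env_hist, env_fut, models,
                               const = energetics_constants()) {
  if (!isTRUE(all.equal(env_hist$grid, env_fut$grid)))
    stop("the two periods must share one grid", call. = FALSE)
  kin <- track_kinematics(tag, const)
  daylen <- day_length_hours(kin$lat, kin$date)
  one_period <- function(env) {
    ev <- env_at(env, kin$lat, kin$lon, kin$date)
    t_amb <- temp_at_depth(ev$sst, ev$t200, kin$mean_depth_m)
    hif <- pmax(0, as.numeric(predict(models$hif, data.frame(
      mesozoo = ev$mesozoo, length_cm = kin$length_cm,
      day_length = daylen))))
    ingested <- predict_ingestion(models$ingestion, hif, t_amb,
                                  const$pct_finfish)
    mo2 <- pmax(0, predict(models$cost, data.frame(
      temperature = t_amb, speed = kin$speed_bls)))
    cost <- mo2_to_kj(mo2, kin$weight_kg, 24, const)
    daily_balance(ingested, cost, const)
  }
  kin$balance_hist_kj <- one_period(env_hist)
  kin$balance_fut_kj <- one_period(env_fut)
  kin$delta_balance_kj <- kin$balance_fut_kj - kin$balance_hist_kj
  kin$balance_hist_kj_7d <- smooth_distances(kin$balance_hist_kj)
  kin$balance_fut_kj_7d <- smooth_distances(kin$balance_fut_kj)
  kin$delta_balance_kj_7d <- smooth_distances(kin$delta_balance_kj)
  kin
}
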