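#' Build a feeding schedule whose daily heat increment tracks forage fields
#'
#' One feeding pulse per day, placed around local midday, whose analytic
#' area (the daily Heat Increment of Feeding, degree C x hour) follows the
#' generator's foraging link: `hif = h0 + h_zoo * mesozoo + h_daylen *
#' day_length + h_length * length`, truncated at zero. Pulse height is fixed
#' (`cfg$hif$pulse_height`); duration carries the signal.
#'
#' @param cfg a [synth_config()]
#' @param daily data.frame with `day`, `date`, `lat`, `lon`, `length_cm`
#' @param env an `env_field_set` to sample mesozooplankton from
#' @return data.frame with columns `day`, `excess_c`, `duration_h`, `shape`,
#'   `start_hour` (one row per day with a positive target)
#' @export
make_feeding_schedule <- function(cfg, daily, env) {
  hp <- cfg$hif
  zoo <- env_at(env, daily$lat, daily$lon, daily$date, vars = "mesozoo")$mesozoo
  daylen <- day_length_hours(daily$lat, daily$date)
  target <- pmax(0, hp$h0 + hp$h_zoo * zoo + hp$h_daylen * daylen +
                   hp$h_length * daily$length_cm)
  keep <- target > 1e-9
  data.frame(day = daily$day[keep],
             excess_c = hp$pulse_height,
             duration_h = target[keep] / hp$pulse_height,
             shape = "trapezoid",
             start_hour = hp$pulse_start_hour)
}

# per-minute excess (deg C) for one pulse, exact trapezoid-integrable shape;
# returns the contribution on integer local-minute grid `minute_local`
pulse_excess <- function(minute_local, start_min, height, duration_h,
                         shape, ramp_min) {
  dur_min <- round(duration_h * 60)
  if (identical(shape, "rect") || dur_min <= ramp_min) {
    # half-open [start, start + dur): trapezoid integral = height * dur exactly
    return(ifelse(minute_local >= start_min &
                    minute_local < start_min + dur_min, height, 0))
  }
  flat <- dur_min - ramp_min              # area = height * (flat + ramp)
  t <- minute_local - start_min
  up <- t >= 0 & t < ramp_min
  top <- t >= ramp_min & t <= ramp_min + flat
  down <- t > ramp_min + flat & t <= 2 * ramp_min + flat
  out <- numeric(length(t))
  out[up] <- height * t[up] / ramp_min
  out[top] <- height
  out[down] <- height * (2 * ramp_min + flat - t[down]) / ramp_min
  out
}

pulse_extent_min <- function(duration_h, shape, ramp_min) {
  dur_min <- round(duration_h * 60)
  if (identical(shape, "rect") || dur_min <= ramp_min) dur_min
  else dur_min + ramp_min
}

#' Generate one synthetic archival-tag record
#'
#' Simulates a tagged juvenile albacore: a seeded daily random walk with a
#' seasonal east-west drift kept inside the configured grid; a 1-min depth
#' trace alternating a deep daytime mean (an increasing function of the
#' oxygen-surface depth and T200 at the fish's position) and a shallow
#' nighttime mean, with a sinusoidal within-period dive oscillation; a 1-min
#' body-temperature trace equal to a constant fasting baseline plus the
#' scheduled feeding pulses plus Gaussian noise; and an ambient-temperature
#' trace from the linear SST/T200 profile at the instantaneous depth. Fork
#' length grows linearly between release and recapture. Day/night and pulse
#' timing use longitude-derived local solar time.
#'
#' Feeding pulses are trapezoid-shaped by default with an exact closed-form
#' area, recorded per day in the truth store (`$truth$daily_hif`), so every
#' downstream daily HIF, cost, and balance is analytically computable in
#' noise-free mode. Overlapping pulses on one day are rejected to keep the
#' per-day area analytic.
#'
#' @param cfg a [synth_config()]
#' @param fish_id label
#' @param feeding_schedule data.frame as returned by
#'   [make_feeding_schedule()]; `NULL` builds the default schedule; an
#'   empty data.frame means a fasting fish.
#' @param env `env_field_set` the fish experiences; default: the historical
#'   observation-like fields from `cfg`.
#' @param release_date first day of deployment
#' @return an object of class `tag_record` with `$daily` (day, date, lat,
#'   lon, length_cm), `$minute` (timestamp, depth_m, body_temp_C,
#'   ambient_temp_C), deployment metadata, and a `$truth` store holding the
#'   generating parameters, per-day analytic HIF, and the baseline.
#' @examples
#' cfg <- synth_config(seed = 1, deployment_days = 14, resolution = 5)
#' tag <- generate_tag_record(cfg, "f01", feeding_schedule = data.frame())
#' nrow(tag$minute) == 14 * 1440
#' @export
generate_tag_record <- function(cfg, fish_id, feeding_schedule = NULL,
                                env = NULL,
                                release_date = as.Date("2005-06-01")) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(env)) env <- generate_env_fields(cfg, "historical", "obs")
  g <- cfg$grid
  nd <- cfg$deployment_days
  dates <- release_date + seq_len(nd) - 1

  ## --- daily positions: seeded random walk + seasonal east-west drift ----
  daily <- with_seed(derive_seed(cfg$seed, "track", fish_id), {
    span <- g$n_lon * g$resolution
    lat_span <- diff(g$lat_range)
    arc <- numeric(nd); lat <- numeric(nd)
    arc[1] <- span * (0.55 + 0.25 * stats::runif(1))
    lat[1] <- mean(g$lat_range) + 0.15 * lat_span * (stats::runif(1) - 0.5)
    doy <- as.POSIXlt(dates)$yday + 1
    drift <- -0.35 * sin(2 * pi * (doy - 80) / 365.25)  # westward in summer
    reflect <- function(x, lo, hi) {
      w <- hi - lo
      y <- (x - lo) %% (2 * w)
      lo + ifelse(y > w, 2 * w - y, y)
    }
    for (d in 2:nd) {
      arc[d] <- reflect(arc[d - 1] + drift[d] + stats::rnorm(1, 0, 0.3),
                        0.5 * g$resolution, span - 0.5 * g$resolution)
      lat[d] <- reflect(lat[d - 1] + stats::rnorm(1, 0, 0.2),
                        g$lat_range[1] + 0.5 * g$resolution,
                        g$lat_range[2] - 0.5 * g$resolution)
    }
    data.frame(day = seq_len(nd), date = dates,
               lat = lat, lon = wrap_lon(g$lon_range[1] + arc))
  })
  daily$length_cm <- cfg$release_length_cm + cfg$growth_cm_day * (daily$day - 1)

  ## --- feeding schedule ------------------------------------------------
  if (is.null(feeding_schedule))
    feeding_schedule <- make_feeding_schedule(cfg, daily, env)
  fs <- as.data.frame(feeding_schedule)
  if (nrow(fs)) {
    if (!all(c("day", "excess_c", "duration_h") %in% names(fs)))
      stop("feeding_schedule needs columns day, excess_c, duration_h")
    if (is.null(fs$shape)) fs$shape <- "trapezoid"
    if (is.null(fs$start_hour)) fs$start_hour <- cfg$hif$pulse_start_hour
    if (any(fs$day < 1 | fs$day > nd))
      stop("feeding events must fit within the deployment")
    if (any(fs$duration_h >= 24)) stop("pulse durations must be < 24 h")
    ramp <- cfg$hif$pulse_ramp_min
    for (d in unique(fs$day)) {
      ev <- fs[fs$day == d, , drop = FALSE]
      if (nrow(ev) > 1) {
        s <- round(ev$start_hour * 60)
        e <- s + mapply(pulse_extent_min, ev$duration_h, ev$shape,
                        MoreArgs = list(ramp_min = ramp))
        o <- order(s)
        if (any(s[o][-1] < e[o][-nrow(ev)]))
          stop("overlapping feeding pulses on day ", d, " rejected")
      }
    }
  }

  ## --- minute traces ----------------------------------------------------
  # grid anchored at local solar midnight of the release position
  t0 <- as.POSIXct(paste(release_date, "00:00:00"), tz = "UTC") -
    daily$lon[1] / 15 * 3600
  minute_of_day <- seq_len(1440) - 1
  dp <- cfg$depth
  envd <- env_at(env, daily$lat, daily$lon, daily$date)
  day_mean <- clamp(dp$day_d0 + dp$day_o2 * envd$o2depth_3p5 +
                      dp$day_t200 * (envd$t200 - 10), 0, 200)
  night_mean <- pmax(dp$night_d0 + dp$night_t200 * (envd$t200 - 10), 0)
  daylen <- day_length_hours(daily$lat, daily$date)

  n_min <- nd * 1440L
  depth <- numeric(n_min); excess <- numeric(n_min)
  is_day <- logical(n_min)
  for (d in seq_len(nd)) {
    idx <- (d - 1) * 1440L + seq_len(1440L)
    # exact local solar minute at this day's longitude (for the diel split);
    # pulses use the offset rounded to a whole minute so sampled pulses sit
    # exactly on the integer-minute grid and their trapezoid-rule integral
    # equals the closed-form area
    off_exact <- (daily$lon[d] - daily$lon[1]) * 4
    h_local <- ((minute_of_day + off_exact) %% 1440) / 60
    m_local <- (minute_of_day + round(off_exact)) %% 1440
    day_flag <- abs(h_local - 12) < daylen[d] / 2
    # dive oscillation completes an integer number of cycles within each
    # contiguous day/night segment, so the phase mean equals the diel link
    # exactly (noise-free analytic contract)
    runs <- rle(day_flag)
    osc <- numeric(1440L); pos <- 1L
    for (L in runs$lengths) {
      cyc <- max(1, round(L / dp$osc_period_min))
      osc[pos:(pos + L - 1L)] <- sin(2 * pi * cyc * (0:(L - 1L)) / L)
      pos <- pos + L
    }
    depth[idx] <- ifelse(day_flag,
                         day_mean[d] + dp$osc_amp_day * osc,
                         night_mean[d] + dp$osc_amp_night * osc)
    is_day[idx] <- day_flag
    ev <- if (nrow(fs)) fs[fs$day == d, , drop = FALSE] else fs
    if (nrow(ev)) {
      for (k in seq_len(nrow(ev)))
        excess[idx] <- excess[idx] +
          pulse_excess(m_local, round(ev$start_hour[k] * 60), ev$excess_c[k],
                       ev$duration_h[k], ev$shape[k], cfg$hif$pulse_ramp_min)
    }
  }
  depth <- pmax(depth, 0)

  day_rep <- rep(seq_len(nd), each = 1440L)
  sst_min <- envd$sst[day_rep]; t200_min <- envd$t200[day_rep]
  ambient <- temp_at_depth(sst_min, t200_min, depth)

  noise <- with_seed(derive_seed(cfg$seed, "trace", fish_id), list(
    depth = if (cfg$noise_sd$depth > 0)
      stats::rnorm(n_min, 0, cfg$noise_sd$depth) else 0,
    body = if (cfg$noise_sd$body_temp > 0)
      stats::rnorm(n_min, 0, cfg$noise_sd$body_temp) else 0,
    amb = if (cfg$noise_sd$ambient > 0)
      stats::rnorm(n_min, 0, cfg$noise_sd$ambient) else 0))

  minute <- data.frame(
    timestamp = t0 + 60 * (seq_len(n_min) - 1),
    depth_m = pmax(depth + noise$depth, 0),
    body_temp_C = cfg$body_temp_baseline + excess + noise$body,
    ambient_temp_C = ambient + noise$amb)

  hif_true <- numeric(nd)
  if (nrow(fs)) {
    a <- tapply(fs$excess_c * fs$duration_h, fs$day, sum)
    hif_true[as.integer(names(a))] <- a
  }

  structure(list(
    fish_id = fish_id,
    release_date = release_date, recapture_date = dates[nd],
    release_length_cm = daily$length_cm[1],
    recapture_length_cm = daily$length_cm[nd],
    daily = daily, minute = minute,
    truth = list(baseline = cfg$body_temp_baseline,
                 daily_hif = data.frame(day = seq_len(nd), date = dates,
                                        hif_true = hif_true),
                 day_depth_mean = day_mean, night_depth_mean = night_mean,
                 is_day = is_day, schedule = fs,
                 depth_params = dp, hif_params = cfg$hif)),
    class = "tag_record")
}

#' Generate a set of tag records
#'
#' @param cfg a [synth_config()]; `cfg$n_fish` records are produced with
#'   default feeding schedules.
#' @param env optional shared `env_field_set`
#' @param release_date first deployment day (shared)
#' @return named list of `tag_record`s
#' @export
generate_tag_records <- function(cfg, env = NULL,
                                 release_date = as.Date("2005-06-01")) {
  if (is.null(env)) env <- generate_env_fields(cfg, "historical", "obs")
  ids <- sprintf("fish%02d", seq_len(cfg$n_fish))
  stats::setNames(lapply(ids, function(id)
    generate_tag_record(cfg, id, env = env, release_date = release_date)), ids)
}

#' @export
print.tag_record <- function(x, ...) {
  cat(sprintf("<tag_record> %s: %d days (%s to %s), %d minute samples\n",
              x$fish_id, nrow(x$daily), x$release_date, x$recapture_date,
              nrow(x$minute)))
  invisible(x)
}

#' Write / read a tag record as the two-CSV tag dialect
#'
#' `<prefix>_daily.csv` holds `date, lat, lon, length_cm`;
#' `<prefix>_minute.csv` holds `timestamp, depth_m, body_temp_C,
#' ambient_temp_C` at 1-min resolution (UTC, ISO 8601).
#'
#' @param tag a `tag_record`
#' @param prefix file path prefix
#' @return `write_tag_record()` the prefix, invisibly; `read_tag_record()` a
#'   `tag_record` (without the synthetic truth store).
#' @export
write_tag_record <- function(tag, prefix) {
  utils::write.csv(tag$daily[c("date", "lat", "lon", "length_cm")],
                   paste0(prefix, "_daily.csv"), row.names = FALSE)
  m <- tag$minute
  m$timestamp <- format(m$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(m, paste0(prefix, "_minute.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_tag_record
#' @param fish_id id to attach on read
#' @export
read_tag_record <- function(prefix, fish_id = basename(prefix)) {
  daily <- utils::read.csv(paste0(prefix, "_daily.csv"))
  daily$date <- as.Date(daily$date)
  daily$day <- seq_len(nrow(daily))
  minute <- utils::read.csv(paste0(prefix, "_minute.csv"))
  minute$timestamp <- as.POSIXct(minute$timestamp, tz = "UTC",
                                 format = "%Y-%m-%dT%H:%M:%OSZ")
  structure(list(fish_id = fish_id,
                 release_date = daily$date[1],
                 recapture_date = daily$date[nrow(daily)],
                 release_length_cm = daily$length_cm[1],
                 recapture_length_cm = daily$length_cm[nrow(daily)],
                 daily = daily, minute = minute, truth = NULL),
            class = "tag_record")
}
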