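#' Temperature at depth from SST and upper-200 m mean temperature
#'
#' Linear vertical profile constrained by the two quantities the gridded
#' fields provide: `T(0) = SST` and the 0-200 m depth average equal to
#' T200, i.e. `T(z) = SST + z * (T200 - SST) / 100`. Depths are clamped to
#' [0, 200] m before evaluation. This profile rule is a documented
#' stand-in; real thermoclines are not linear.
#'
#' @param sst sea-surface temperature, degrees C
#' @param t200 upper-200 m mean temperature, degrees C
#' @param z depth, m
#' @return temperature at depth, degrees C
#' @examples
#' temp_at_depth(20, 14, 200)   # 8
#' @export
temp_at_depth <- function(sst, t200, z) {
  z <- clamp(z, 0, 200)
  sst + z * (t200 - sst) / 100
}

#' Grid-cell areas on the sphere
#'
#' `area = R^2 * cos(lat) * dlon * dlat` (radians), R = 6371 km, for a
#' regular cell-centered lat/lon grid.
#'
#' @param lat cell-center latitudes, degrees
#' @param resolution cell size, degrees (applied to both axes unless
#'   `resolution_lon` is given)
#' @param resolution_lon longitudinal cell size, degrees
#' @param radius_km sphere radius, km
#' @return vector of cell areas (km^2) aligned with `lat`
#' @examples
#' cell_areas(0, 1)   # ~12364 km^2
#' @export
cell_areas <- function(lat, resolution, resolution_lon = resolution,
                       radius_km = 6371) {
  to_rad <- pi / 180
  radius_km^2 * cos(lat * to_rad) * (resolution_lon * to_rad) *
    (resolution * to_rad)
}

# per-cell area matrix [n_lon x n_lat] for an env_field_set / map grid
cell_area_matrix <- function(grid) {
  a <- cell_areas(grid$lat_range[1] +
                    grid$resolution * (seq_len(grid$n_lat) - 0.5),
                  grid$resolution)
  outer(rep(1, grid$n_lon), a)
}

#' Project the energetics chain onto gridded fields
#'
#' Applies the fitted model chain per grid cell and month for a reference
#' fish: diel depths from the depth models (clamped to [0, 200] m), ambient
#' temperatures at those depths via the linear profile, movement cost as
#' day-length-weighted day/night oxygen consumption converted to kJ, the
#' Heat Increment of Feeding from the foraging model (mesozooplankton,
#' reference length, day length), ingested energy from the ingestion model
#' at the daytime ambient temperature and the assumed diet, and the daily
#' balance from the accounting identity. Cells whose SST falls outside the
#' favorable envelope are flagged in the thermal mask (inclusive bounds).
#' Moon illumination and day length are evaluated at the mid-month date of
#' a nominal year.
#'
#' @param env an `env_field_set` carrying `sst`, `t200`, `o2depth_3p5`,
#'   `mesozoo`
#' @param models model list from [fit_energetics_models()]
#' @param const an [energetics_constants()]
#' @param ref reference [fish_state()]; default built from `const`
#' @param months months to project (default: all in `env`)
#' @param coefs optional named list of coefficient draws
#'   (`depth_day`, `depth_night`, `cost`, `hif`, `ingestion`) for posterior
#'   ensemble members
#' @return list of `energetics_map` objects, one per month, each holding
#'   per-cell matrices `sst`, `day_depth`, `night_depth`, `t_day`,
#'   `t_night`, `cost`, `hif`, `ingested`, `balance` and logical `mask`
#' @export
project_energetics <- function(env, models, const = energetics_constants(),
                               ref = NULL, months = NULL, coefs = list()) {
  needed <- c("sst", "t200", "o2depth_3p5", "mesozoo")
  miss <- setdiff(needed, names(env$fields))
  if (length(miss))
    stop("missing environmental field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(ref)) ref <- fish_state(const$ref_length_cm,
                                      const$ref_weight_kg, const)
  if (is.null(months)) months <- env$months
  g <- env$grid
  lat_mat <- outer(rep(1, g$n_lon), env$lat)

  lapply(months, function(m) {
    mid_date <- as.Date(sprintf("2005-%02d-15", ((m - 1) %% 12) + 1))
    sst <- env$fields$sst[, , m]
    t200 <- env$fields$t200[, , m]
    o2d <- env$fields$o2depth_3p5[, , m]
    zoo <- env$fields$mesozoo[, , m]
    moon <- moon_fraction(mid_date)
    daylen <- matrix(day_length_hours(as.vector(lat_mat), mid_date),
                     g$n_lon, g$n_lat)

    nd <- data.frame(t200 = as.vector(t200), moon = moon,
                     o2depth_3p5 = as.vector(o2d))
    day_depth <- clamp(predict(models$depth_day, nd,
                               coefs = coefs$depth_day), 0, 200)
    night_depth <- clamp(predict(models$depth_night, nd,
                                 coefs = coefs$depth_night), 0, 200)
    t_day <- temp_at_depth(as.vector(sst), as.vector(t200), day_depth)
    t_night <- temp_at_depth(as.vector(sst), as.vector(t200), night_depth)
    mo2_day <- pmax(0, predict(models$cost,
                               data.frame(temperature = t_day,
                                          speed = const$speed_day),
                               coefs = coefs$cost))
    mo2_night <- pmax(0, predict(models$cost,
                                 data.frame(temperature = t_night,
                                            speed = const$speed_night),
                                 coefs = coefs$cost))
    dl <- as.vector(daylen)
    cost <- mo2_to_kj(mo2_day, ref$weight_kg, dl, const) +
      mo2_to_kj(mo2_night, ref$weight_kg, 24 - dl, const)
    hif <- pmax(0, as.numeric(predict(models$hif,
                                      data.frame(mesozoo = as.vector(zoo),
                                                 length_cm = ref$length_cm,
                                                 day_length = dl),
                                      coefs = coefs$hif)))
    ingested <- predict_ingestion(models$ingestion, hif, t_day,
                                  const$pct_finfish, coefs = coefs$ingestion)
    balance <- daily_balance(ingested, cost, const)
    shape <- function(x) matrix(x, g$n_lon, g$n_lat)
    structure(list(
      lon = env$lon, lat = env$lat, grid = g, month = m,
      period = env$period, source_id = env$source_id,
      fields = list(sst = sst,
                    day_depth = shape(day_depth),
                    night_depth = shape(night_depth),
                    t_day = shape(t_day), t_night = shape(t_night),
                    cost = shape(cost), hif = shape(hif),
                    ingested = shape(ingested), balance = shape(balance),
                    mask = sst >= const$thermal_min &
                      sst <= const$thermal_max)),
      class = "energetics_map")
  })
}

#' @export
print.energetics_map <- function(x, ...) {
  cat(sprintf(
    "<energetics_map> %s/%s month %d: %d x %d cells, %d favorable\n",
    x$source_id, x$period, x$month, length(x$lon), length(x$lat),
    sum(x$fields$mask)))
  invisible(x)
}

default_seasons <- function() {
  list(DJF = c(12, 1, 2), MAM = 3:5, JJA = 6:8, SON = 9:11)
}

# average monthly maps into one seasonal map; mask from seasonal-mean SST
seasonal_map <- function(maps, months, const, season_label) {
  sel <- maps[vapply(maps, `[[`, 0L, "month") %in% months]
  if (!length(sel)) stop("no maps for season ", season_label, call. = FALSE)
  avg <- function(name)
    Reduce(`+`, lapply(sel, function(m) m$fields[[name]])) / length(sel)
  fields <- lapply(stats::setNames(nm = c("sst", "day_depth", "night_depth",
                                          "t_day", "t_night", "cost", "hif",
                                          "ingested", "balance")), avg)
  fields$mask <- fields$sst >= const$thermal_min &
    fields$sst <= const$thermal_max
  structure(list(lon = sel[[1]]$lon, lat = sel[[1]]$lat,
                 grid = sel[[1]]$grid, month = NA_integer_,
                 season = season_label, period = sel[[1]]$period,
                 source_id = sel[[1]]$source_id, fields = fields),
            class = "energetics_map")
}

#' Seasonal habitat-area and energy-balance change
#'
#' For each season: the area (km^2) of thermally favorable habitat (SST
#' within the envelope, evaluated on the seasonal-mean SST) in each period,
#' the area change and percent change, the area-weighted mean daily kJ
#' balance inside each period's own mask, their difference, and the
#' area-weighted mean balance change inside the intersection mask (cells
#' favorable in both periods — the "consistently favorable" habitat).
#' Seasons with an empty mask are flagged and their weighted means reported
#' as missing.
#'
#' @param maps_hist,maps_fut monthly map lists from [project_energetics()]
#'   on a common grid
#' @param const an [energetics_constants()]
#' @param seasons named list of month vectors (default boreal DJF/MAM/JJA/
#'   SON)
#' @return data.frame, one row per season
#' @export
habitat_change <- function(maps_hist, maps_fut,
                           const = energetics_constants(),
                           seasons = default_seasons()) {
  g <- maps_hist[[1]]$grid
  if (!isTRUE(all.equal(g, maps_fut[[1]]$grid)))
    stop("periods must share one grid", call. = FALSE)
  areas <- cell_area_matrix(g)
  rows <- lapply(names(seasons), function(sn) {
    mh <- seasonal_map(maps_hist, seasons[[sn]], const, sn)
    mf <- seasonal_map(maps_fut, seasons[[sn]], const, sn)
    wmean <- function(x, mask) {
      if (!any(mask)) return(NA_real_)
      sum(x[mask] * areas[mask]) / sum(areas[mask])
    }
    a_h <- sum(areas[mh$fields$mask])
    a_f <- sum(areas[mf$fields$mask])
    both <- mh$fields$mask & mf$fields$mask
    b_h <- wmean(mh$fields$balance, mh$fields$mask)
    b_f <- wmean(mf$fields$balance, mf$fields$mask)
    data.frame(
      season = sn, source_id = maps_hist[[1]]$source_id,
      area_hist_km2 = a_h, area_fut_km2 = a_f,
      delta_area_km2 = a_f - a_h,
      pct_delta_area = if (a_h > 0) 100 * (a_f - a_h) / a_h else NA_real_,
      balance_hist_kj = b_h, balance_fut_kj = b_f,
      delta_balance_kj = b_f - b_h,
      delta_balance_consistent_kj =
        wmean(mf$fields$balance - mh$fields$balance, both),
      empty_mask = !any(mh$fields$mask) || !any(mf$fields$mask))
  })
  do.call(rbind, rows)
}

#' Summarize habitat change across an ensemble of field sources
#'
#' Cross-source mean and t-based 95% confidence interval of the change
#' metrics, per season, with per-source values retained in the input. With
#' a single source the CI is suppressed. Seasons where sources disagree on
#' the direction of the balance change are flagged.
#'
#' @param summaries data.frame rbind of [habitat_change()] results across
#'   sources
#' @param level confidence level
#' @return data.frame with one row per season x metric: `mean`, `ci_lo`,
#'   `ci_hi`, `n_sources`, `direction_disagreement`
#' @export
ensemble_summary <- function(summaries, level = 0.95) {
  metrics <- c("delta_area_km2", "pct_delta_area", "delta_balance_kj",
               "delta_balance_consistent_kj")
  rows <- list()
  for (sn in unique(summaries$season)) {
    sub <- summaries[summaries$season == sn, , drop = FALSE]
    db <- sub$delta_balance_kj[is.finite(sub$delta_balance_kj)]
    disagree <- length(db) > 1 && any(db > 0) && any(db < 0)
    for (met in metrics) {
      x <- sub[[met]][is.finite(sub[[met]])]
      n <- length(x)
      if (n == 0) next
      m <- mean(x)
      if (n >= 2) {
        half <- stats::qt(1 - (1 - level) / 2, df = n - 1) *
          stats::sd(x) / sqrt(n)
        ci <- c(m - half, m + half)
      } else ci <- c(NA_real_, NA_real_)
      rows[[length(rows) + 1]] <-
        data.frame(season = sn, metric = met, mean = m,
                   ci_lo = ci[1], ci_hi = ci[2], n_sources = n,
                   direction_disagreement = disagree)
    }
  }
  do.call(rbind, rows)
}

#' Write an energetics map as plain text
#'
#' Long-format CSV (`lon, lat`, one column per field) with a JSON metadata
#' sidecar.
#'
#' @param map an `energetics_map`
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_energetics_map <- function(map, path) {
  d <- expand.grid(lon = map$lon, lat = map$lat, KEEP.OUT.ATTRS = FALSE)
  for (v in names(map$fields)) d[[v]] <- as.vector(map$fields[[v]])
  utils::write.csv(d, path, row.names = FALSE)
  meta <- list(period = map$period, source_id = map$source_id,
               month = map$month, season = map$season %||% NA)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
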