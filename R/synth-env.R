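#' Generate gridded monthly environmental fields
#'
#' Builds the four ocean predictors the energetics chain consumes — SST,
#' upper-200 m mean temperature (T200), depth of the 3.5 ml L-1 dissolved
#' oxygen surface, and upper-200 m mesozooplankton biomass — as monthly
#' fields on the cell-centered grid in `cfg`. The deterministic structure is:
#' SST decreases poleward with a sinusoidal seasonal cycle; T200 sits a fixed
#' stratification offset below SST; mesozooplankton increases poleward and
#' toward the eastern boundary with a spring-summer peak; the oxygen surface
#' shoals inside a prescribed offshore longitude band. The future period adds
#' `cfg$warming_offset` to SST and T200 and multiplies mesozooplankton by the
#' latitude-banded `cfg$zoo_trend`.
#'
#' Distinct `source_id`s (emulating different earth system models) receive a
#' deterministic SST bias and mesozooplankton scale derived from the id,
#' applied identically to both periods, plus their own noise realization.
#' Noise is drawn from a period-independent stream, so with
#' `warming_offset = 0` and unit `zoo_trend` the future fields are identical
#' to the historical ones under the same seed.
#'
#' @param cfg a [synth_config()]
#' @param period `"historical"` or `"future"`
#' @param source_id label for the field source (e.g. `"esm1"`); `"obs"` is
#'   conventionally the unbiased observation-like source.
#' @return an object of class `env_field_set`: grid vectors `lon`, `lat`,
#'   month index, and a `fields` list of `n_lon x n_lat x months` arrays
#'   named `sst`, `t200`, `o2depth_3p5`, `mesozoo`, with the generating
#'   parameters stored under `$params`.
#' @examples
#' env <- generate_env_fields(synth_config(seed = 1, resolution = 5), "historical")
#' dim(env$fields$sst)
#' @export
generate_env_fields <- function(cfg, period = c("historical", "future"),
                                source_id = "obs") {
  if (!inherits(cfg, "synth_config")) stop("cfg must be a synth_config")
  period <- match.arg(period)
  g <- cfg$grid
  p <- cfg$env
  months <- seq_len(cfg$months)

  # source-specific deterministic biases (identical in both periods)
  sst_bias <- if (identical(source_id, "obs")) 0 else
    p$source_sst_bias * unit_hash(source_id, salt = 1)
  zoo_scale <- if (identical(source_id, "obs")) 1 else
    1 + p$source_zoo_scale * unit_hash(source_id, salt = 2)

  east_frac <- (seq_len(g$n_lon) - 0.5) / g$n_lon
  arc_deg <- east_frac * g$n_lon * g$resolution
  lat <- g$lat

  dims <- c(g$n_lon, g$n_lat, cfg$months)
  seas <- function(amp, phase, m) amp * cos(2 * pi * (m - phase) / 12)

  sst <- array(0, dims); zoo <- array(0, dims); o2d <- array(0, dims)
  for (m in months) {
    sst_m <- outer(rep(1, g$n_lon),
                   p$sst0 - p$sst_lat_slope * (lat - g$lat_range[1])) +
      seas(p$sst_seas_amp, p$sst_phase_month, m)
    zoo_m <- outer(p$zoo_east * east_frac,
                   p$zoo0 + p$zoo_lat * (lat - g$lat_range[1]), `+`) +
      seas(p$zoo_seas_amp, p$zoo_phase_month, m)
    o2_m <- outer(p$o2_base - p$o2_dip *
                    exp(-((arc_deg - p$o2_band_center_frac * max(arc_deg)) /
                            p$o2_band_width_deg)^2),
                  rep(1, g$n_lat))
    sst[, , m] <- sst_m
    zoo[, , m] <- zoo_m
    o2d[, , m] <- o2_m
  }
  sst <- sst + sst_bias
  zoo <- zoo * zoo_scale

  if (period == "future") {
    sst <- sst + cfg$warming_offset
    mid_lat <- mean(g$lat_range)
    trend <- ifelse(lat < mid_lat, cfg$zoo_trend[["south"]],
                    cfg$zoo_trend[["north"]])
    zoo <- zoo * rep(rep(trend, each = g$n_lon), cfg$months)
  }
  t200 <- sst - p$strat_offset

  # period-independent noise stream: zero perturbation => identical periods
  noise <- function(sd) {
    if (sd == 0) return(0)
    array(stats::rnorm(prod(dims), 0, sd), dims)
  }
  fields <- with_seed(derive_seed(cfg$seed, "env", source_id), list(
    sst = sst + noise(cfg$noise_sd$sst),
    t200 = t200 + noise(cfg$noise_sd$t200),
    o2depth_3p5 = pmax(o2d + noise(cfg$noise_sd$o2depth), 5),
    mesozoo = pmax(zoo + noise(cfg$noise_sd$mesozoo), 1)))
  stopifnot(all(vapply(fields, function(f) all(is.finite(f)), logical(1))))

  structure(list(
    lon = g$lon, lat = lat, months = months,
    grid = g, period = period, source_id = source_id,
    fields = fields,
    params = c(p, list(warming_offset = cfg$warming_offset,
                       zoo_trend = cfg$zoo_trend, sst_bias = sst_bias,
                       zoo_scale = zoo_scale))),
    class = "env_field_set")
}

#' @export
print.env_field_set <- function(x, ...) {
  cat(sprintf("<env_field_set> %s / %s: %d x %d cells, %d months [%s]\n",
              x$source_id, x$period, length(x$lon), length(x$lat),
              length(x$months), paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

# nearest-cell indices for points; counts out-of-grid fallbacks
env_cell_index <- function(env, lat, lon) {
  g <- env$grid
  rel <- (lon - g$lon_range[1]) %% 360
  i <- floor(rel / g$resolution) + 1
  outside_lon <- rel > g$n_lon * g$resolution
  i <- clamp(i, 1, g$n_lon)
  j <- floor((lat - g$lat_range[1]) / g$resolution) + 1
  outside_lat <- j < 1 | j > g$n_lat
  j <- clamp(j, 1, g$n_lat)
  list(i = i, j = j, n_outside = sum(outside_lon | outside_lat))
}

# fractional month position of a date within a 12-month climatology
month_position <- function(date) {
  lt <- as.POSIXlt(date)
  doy <- lt$yday + 0.5
  (doy / 365.25) * 12
}

#' Sample environmental fields at points and dates
#'
#' Nearest-cell lookup in space, linear interpolation in time between
#' climatological month midpoints (cyclic over the year). Points outside the
#' grid fall back to the nearest cell; the fallback count is returned as the
#' `"n_outside"` attribute.
#'
#' @param env an `env_field_set` with 12 monthly fields
#' @param lat,lon point coordinates, degrees (recycled to a common length)
#' @param date `Date` vector
#' @param vars which variables to sample (default all four)
#' @return data.frame with one column per variable
#' @export
env_at <- function(env, lat, lon, date,
                   vars = c("sst", "t200", "o2depth_3p5", "mesozoo")) {
  stopifnot(inherits(env, "env_field_set"))
  if (length(env$months) != 12L)
    stop("env_at() requires a 12-month climatology")
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); date <- rep_len(date, n)
  ix <- env_cell_index(env, lat, lon)
  pos <- month_position(date)                      # in [0, 12)
  m_lo <- ((floor(pos - 0.5)) %% 12) + 1           # month whose midpoint <= pos
  m_hi <- (m_lo %% 12) + 1
  w_hi <- (pos - 0.5) %% 1
  out <- lapply(vars, function(v) {
    f <- env$fields[[v]]
    lo <- f[cbind(ix$i, ix$j, m_lo)]
    hi <- f[cbind(ix$i, ix$j, m_hi)]
    (1 - w_hi) * lo + w_hi * hi
  })
  names(out) <- vars
  out <- as.data.frame(out)
  attr(out, "n_outside") <- ix$n_outside
  out
}

#' Write / read environmental fields as plain text
#'
#' Long-format CSV (`lon, lat, month, sst, t200, o2depth_3p5, mesozoo`) plus
#' a JSON sidecar (`<path>.meta.json`) carrying the grid definition, period
#' and source id, so a field set round-trips through text files.
#'
#' @param env an `env_field_set`
#' @param path CSV path to write
#' @return `write_env_fields()` returns `path` invisibly;
#'   `read_env_fields()` returns an `env_field_set`.
#' @export
write_env_fields <- function(env, path) {
  stopifnot(inherits(env, "env_field_set"))
  grid <- expand.grid(lon = env$lon, lat = env$lat, month = env$months,
                      KEEP.OUT.ATTRS = FALSE)
  for (v in names(env$fields)) grid[[v]] <- as.vector(env$fields[[v]])
  utils::write.csv(grid, path, row.names = FALSE)
  meta <- list(grid = env$grid[c("lat_range", "lon_range", "resolution",
                                 "n_lat", "n_lon")],
               period = env$period, source_id = env$source_id,
               months = length(env$months))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_env_fields
#' @export
read_env_fields <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  d <- utils::read.csv(path)
  g <- meta$grid
  g$lat <- g$lat_range[1] + g$resolution * (seq_len(g$n_lat) - 0.5)
  g$lon <- wrap_lon(g$lon_range[1] + g$resolution * (seq_len(g$n_lon) - 0.5))
  dims <- c(g$n_lon, g$n_lat, meta$months)
  ord <- order(d$month, match(d$lat, g$lat), match(d$lon, g$lon))
  d <- d[ord, ]
  fields <- lapply(c(sst = "sst", t200 = "t200", o2depth_3p5 = "o2depth_3p5",
                     mesozoo = "mesozoo"),
                   function(v) array(d[[v]], dims))
  structure(list(lon = g$lon, lat = g$lat, months = seq_len(meta$months),
                 grid = g, period = meta$period, source_id = meta$source_id,
                 fields = fields, params = NULL),
            class = "env_field_set")
}
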