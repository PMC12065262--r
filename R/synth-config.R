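#' Configuration for the synthetic study system
#'
#' Bundles every tunable of the seeded generators: the spatial grid, the tag
#' deployment, the climate-change perturbation applied to the future period,
#' per-variable noise levels, and the parametric "truth" surfaces behind the
#' respirometry, feeding-trial, diel-depth and foraging (HIF) generators.
#' Downstream recovery tests read truth only from the parameter store attached
#' to each generated object, never from re-derived values.
#'
#' The defaults describe a North Pacific juvenile-albacore study system at
#' desk scale: a 1-degree grid from 15-55N spanning 140E to 110W, a monthly
#' climatology, three tagged fish with 120-day deployments, a +2 degree C
#' end-of-century warming of SST and upper-200 m temperature, and a
#' latitude-banded multiplicative change in mesozooplankton biomass (decline
#' in the subtropics, slight increase poleward) of the size mid-emission
#' scenario ensembles project.
#'
#' @param seed integer root seed; all generator randomness derives from it.
#' @param n_fish number of tagged fish to simulate.
#' @param deployment_days days per deployment (>= 14 so a 7-day moving mean is
#'   definable on both halves of the record).
#' @param lat_range,lon_range grid bounds in degrees. Longitudes may cross the
#'   dateline: `lon_range = c(140, -110)` spans 110 degrees eastward.
#' @param resolution grid spacing, degrees (> 0); cells are cell-centered.
#' @param months number of monthly fields (12 = one climatological year).
#' @param warming_offset degrees C added to future SST and T200 (>= 0).
#' @param zoo_trend named numeric `c(south = , north = )`: multiplicative
#'   future change in mesozooplankton, split at the grid's mid-latitude.
#' @param noise_sd named list of Gaussian noise SDs per generated variable
#'   (`sst`, `t200`, `o2depth`, `mesozoo`, `depth`, `body_temp`, `ambient`,
#'   `mo2`, `kj`). Set all to 0 for analytically exact, noise-free output.
#' @param release_length_cm,growth_cm_day fork length at release and linear
#'   growth rate used for release/recapture length bookkeeping.
#' @param body_temp_baseline fasting visceral temperature, degrees C.
#' @param env,depth,respirometry,trials,hif optional named lists overriding
#'   individual truth-surface parameters (see Details in the package vignette).
#' @return an object of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, resolution = 4)
#' cfg$grid$n_lon
#' @export
synth_config <- function(seed = 42L,
                         n_fish = 3L,
                         deployment_days = 120L,
                         lat_range = c(15, 55),
                         lon_range = c(140, -110),
                         resolution = 1,
                         months = 12L,
                         warming_offset = 2,
                         zoo_trend = c(south = 0.85, north = 1.05),
                         noise_sd = list(),
                         release_length_cm = 75,
                         growth_cm_day = 0.02,
                         body_temp_baseline = 16,
                         env = list(), depth = list(),
                         respirometry = list(), trials = list(), hif = list()) {
  stopifnot_scalar(resolution, "resolution")
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  if (deployment_days < 14)
    stop("deployment_days must be >= 14 (7-day smoothing must be definable)",
         call. = FALSE)
  if (warming_offset < 0) stop("warming_offset must be >= 0", call. = FALSE)
  if (length(lat_range) != 2L || diff(lat_range) <= 0 ||
      any(abs(lat_range) > 90))
    stop("invalid grid bounds: lat_range must be ascending within [-90, 90]",
         call. = FALSE)
  lon_span <- (lon_range[2] - lon_range[1]) %% 360
  if (length(lon_range) != 2L || lon_span <= 0)
    stop("invalid grid bounds: lon_range must span a positive eastward arc",
         call. = FALSE)
  n_lat <- round(diff(lat_range) / resolution)
  n_lon <- round(lon_span / resolution)
  if (n_lat < 1 || n_lon < 1 ||
      abs(n_lat * resolution - diff(lat_range)) > 1e-8 ||
      abs(n_lon * resolution - lon_span) > 1e-8)
    stop("invalid grid bounds: extents must be whole multiples of resolution",
         call. = FALSE)

  noise_defaults <- list(sst = 0.3, t200 = 0.3, o2depth = 8, mesozoo = 40,
                         depth = 4, body_temp = 0.05, ambient = 0.2,
                         mo2 = 12, kj = 120)
  env_defaults <- list(
    sst0 = 29, sst_lat_slope = 0.42, sst_seas_amp = 3, sst_phase_month = 8,
    strat_offset = 3.5,
    zoo0 = 150, zoo_lat = 6, zoo_east = 100, zoo_seas_amp = 80,
    zoo_phase_month = 6,
    o2_base = 320, o2_dip = 140, o2_band_center_frac = 0.4,
    o2_band_width_deg = 15,
    source_sst_bias = 0.8, source_zoo_scale = 0.15)
  depth_defaults <- list(
    day_d0 = 20, day_o2 = 0.45, day_t200 = 1.0,
    night_d0 = 15, night_t200 = 0.8,
    osc_amp_day = 30, osc_amp_night = 5, osc_period_min = 60)
  resp_defaults <- list(b0 = 55, b1 = 28, b2 = 18, b3 = 0.075,
                        n = 240, temp_range = c(10, 25),
                        speed_range = c(0.5, 3))
  trial_defaults <- list(g0 = 800, g1 = 0.02, t0 = 18, g2 = 0.5,
                         n = 300, hif_range = c(0, 5), temp_range = c(10, 25),
                         pct_range = c(40, 100))
  hif_defaults <- list(h0 = 0.2, h_zoo = 0.004, h_daylen = 0.08, h_length = 0,
                       pulse_height = 1.2, pulse_ramp_min = 30,
                       pulse_start_hour = 11)

  merge <- function(def, user) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    def[names(user)] <- user
    def
  }

  cfg <- structure(list(
    seed = as.integer(seed),
    n_fish = as.integer(n_fish),
    deployment_days = as.integer(deployment_days),
    grid = list(
      lat_range = lat_range, lon_range = lon_range, resolution = resolution,
      n_lat = n_lat, n_lon = n_lon,
      lat = lat_range[1] + resolution * (seq_len(n_lat) - 0.5),
      lon = wrap_lon(lon_range[1] + resolution * (seq_len(n_lon) - 0.5))),
    months = as.integer(months),
    warming_offset = warming_offset,
    zoo_trend = zoo_trend,
    noise_sd = merge(noise_defaults, noise_sd),
    release_length_cm = release_length_cm,
    growth_cm_day = growth_cm_day,
    body_temp_baseline = body_temp_baseline,
    env = merge(env_defaults, env),
    depth = merge(depth_defaults, depth),
    respirometry = merge(resp_defaults, respirometry),
    trials = merge(trial_defaults, trials),
    hif = merge(hif_defaults, hif)
  ), class = "synth_config")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  seed %d | %d fish x %d days | grid %dx%d @ %g deg | %d months\n",
              x$seed, x$n_fish, x$deployment_days, x$grid$n_lon, x$grid$n_lat,
              x$grid$resolution, x$months))
  cat(sprintf("  warming_offset %.2f C | zoo_trend south %.2f north %.2f\n",
              x$warming_offset, x$zoo_trend[["south"]], x$zoo_trend[["north"]]))
  invisible(x)
}

#' A noise-free copy of a synthetic configuration
#'
#' Convenience for oracle tests: every `noise_sd` entry set to zero, so all
#' generated quantities equal their parametric truth exactly.
#' @param cfg a [synth_config()] object
#' @return a `synth_config` with all noise SDs zero
#' @export
noise_free <- function(cfg) {
  cfg$noise_sd[] <- 0
  cfg
}
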