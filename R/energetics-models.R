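#' Assemble per-day depth-model training data from tag records
#'
#' Splits each deployment day into daylight and night by longitude-derived
#' local solar time (daylight when the local hour is within half the
#' astronomical day length of solar noon), averages the 1-min depths within
#' each phase, and matches the environmental covariates (T200, depth of the
#' 3.5 ml L-1 oxygen surface) and moon illumination to the fish's daily
#' position and date. Days with unmatched covariates are dropped with a
#' logged count (`"n_dropped"` attribute).
#'
#' @param tags list of `tag_record`s (or a single record)
#' @param env an `env_field_set`
#' @return data.frame with `fish_id`, `date`, `lat`, `lon`, `length_cm`,
#'   `t200`, `o2depth_3p5`, `moon`, `day_depth_m`, `night_depth_m`
#' @export
assemble_depth_data <- function(tags, env) {
  if (inherits(tags, "tag_record")) tags <- list(tags)
  rows <- lapply(tags, function(tag) {
    daily <- tag$daily
    m <- tag$minute
    day_idx <- minute_day_index(tag)
    lon_min <- daily$lon[day_idx]
    lat_min <- daily$lat[day_idx]
    h <- local_solar_hour(m$timestamp, lon_min)
    daylen <- day_length_hours(lat_min, daily$date[day_idx])
    is_day <- abs(h - 12) < daylen / 2
    dd <- tapply(ifelse(is_day, m$depth_m, NA_real_), day_idx, mean,
                 na.rm = TRUE)
    nn <- tapply(ifelse(is_day, NA_real_, m$depth_m), day_idx, mean,
                 na.rm = TRUE)
    keep <- as.integer(names(dd))
    ev <- env_at(env, daily$lat[keep], daily$lon[keep], daily$date[keep],
                 vars = c("t200", "o2depth_3p5"))
    data.frame(fish_id = tag$fish_id, date = daily$date[keep],
               lat = daily$lat[keep], lon = daily$lon[keep],
               length_cm = daily$length_cm[keep],
               t200 = ev$t200, o2depth_3p5 = ev$o2depth_3p5,
               moon = moon_fraction(daily$date[keep]),
               day_depth_m = as.numeric(dd), night_depth_m = as.numeric(nn))
  })
  out <- do.call(rbind, rows)
  cc <- stats::complete.cases(out[c("t200", "o2depth_3p5", "moon",
                                    "day_depth_m", "night_depth_m")])
  res <- out[cc, , drop = FALSE]
  attr(res, "n_dropped") <- sum(!cc)
  res
}

#' Fit the diel depth models (models 1a and 1b)
#'
#' Two additive smooth regressions predicting mean daytime and nighttime
#' fish depth (m) from upper-200 m temperature, moon illumination and the
#' depth of the 3.5 ml L-1 oxygen surface.
#'
#' @param depth_data data.frame from [assemble_depth_data()]
#' @param k basis dimension per smooth
#' @return list with elements `day` and `night`, each a `smooth_model`
#' @export
fit_depth_models <- function(depth_data, k = 6) {
  terms <- list(smooth_term("t200", k = k),
                smooth_term("moon", k = k),
                smooth_term("o2depth_3p5", k = k))
  list(day = fit_gam(depth_data, "day_depth_m", terms,
                     response_units = "m"),
       night = fit_gam(depth_data, "night_depth_m", terms,
                       response_units = "m"))
}

#' Fit the metabolic movement-cost model (model 2)
#'
#' Tensor-product smooth of water temperature and swimming speed predicting
#' mass-specific oxygen consumption (mg O2 kg-1 h-1) from respirometry.
#'
#' @param resp data.frame with `temperature`, `speed`, `mo2` (e.g. from
#'   [generate_respirometry()]); needs >= 50 rows spanning both axes
#' @param k marginal basis dimensions for the tensor product
#' @return a `smooth_model`
#' @export
fit_cost_model <- function(resp, k = c(6, 6)) {
  if (nrow(resp) < 50)
    stop("need >= 50 respirometry rows", call. = FALSE)
  if (length(unique(resp$speed)) < 3 || length(unique(resp$temperature)) < 3)
    stop("respirometry data are one-dimensional: both temperature and ",
         "speed must vary", call. = FALSE)
  model <- fit_gam(resp, "mo2",
                   list(smooth_term(c("temperature", "speed"), k = k)),
                   response_units = "mg O2 kg-1 h-1")
  grd <- expand.grid(
    temperature = seq(model$ranges$temperature[1],
                      model$ranges$temperature[2], length.out = 25),
    speed = seq(model$ranges$speed[1], model$ranges$speed[2],
                length.out = 25))
  if (any(predict(model, grd) <= 0))
    warning("cost model predicts non-positive MO2 inside the training range")
  model
}

#' Assemble daily-HIF training data for the foraging model
#'
#' Joins extracted (or generator-stored) daily Heat Increment of Feeding
#' with upper-200 m mesozooplankton biomass at the fish's position and
#' date, the estimated daily fork length, and astronomical day length.
#' Flagged low-coverage days are dropped.
#'
#' @param tags list of `tag_record`s
#' @param env an `env_field_set`
#' @param daily_hif optional named list (by fish id) of data.frames from
#'   [compute_daily_hif()]; when `NULL` the baseline is estimated and the
#'   HIF extracted from each record's minute trace.
#' @return data.frame with `fish_id`, `date`, `hif`, `mesozoo`, `length_cm`,
#'   `day_length`
#' @export
assemble_hif_data <- function(tags, env, daily_hif = NULL) {
  if (inherits(tags, "tag_record")) tags <- list(tags)
  rows <- lapply(tags, function(tag) {
    dh <- if (!is.null(daily_hif)) daily_hif[[tag$fish_id]] else
      compute_daily_hif(tag, estimate_baseline(tag))
    dh <- dh[!dh$flagged, , drop = FALSE]
    i <- match(dh$date, tag$daily$date)
    ok <- !is.na(i)
    dh <- dh[ok, , drop = FALSE]; i <- i[ok]
    ev <- env_at(env, tag$daily$lat[i], tag$daily$lon[i], dh$date,
                 vars = "mesozoo")
    data.frame(fish_id = tag$fish_id, date = dh$date, hif = dh$hif,
               mesozoo = ev$mesozoo, length_cm = tag$daily$length_cm[i],
               day_length = day_length_hours(tag$daily$lat[i], dh$date))
  })
  do.call(rbind, rows)
}

#' Fit the foraging (HIF) model (model 3)
#'
#' Additive smooth regression predicting daily Heat Increment of Feeding
#' (degree C hour) from mesozooplankton biomass, fish length, and day
#' length.
#'
#' @param hif_data data.frame from [assemble_hif_data()]
#' @param k basis dimension per smooth
#' @return a `smooth_model`
#' @export
fit_hif_model <- function(hif_data, k = 6) {
  fit_gam(hif_data, "hif",
          list(smooth_term("mesozoo", k = k),
               smooth_term("length_cm", k = k),
               smooth_term("day_length", k = k)),
          response_units = "degC hour")
}

#' Fit the energy-ingestion model (model 4)
#'
#' Predicts kJ ingested from the Heat Increment of Feeding, water
#' temperature and percent finfish in the diet. Because meal energy scales
#' with HIF *modulated by* temperature and diet, the model adds
#' interaction-only tensor smooths (HIF x temperature, HIF x diet) to the
#' three marginal smooths; a purely additive surface cannot represent that
#' modulation. Predictions should be floored at zero by consumers (see
#' [predict_ingestion()]): negative meals are basis artifacts.
#'
#' @param trials data.frame with `hif`, `temperature`, `pct_finfish`,
#'   `kj_ingested` (e.g. from [generate_feeding_trials()])
#' @param k basis dimension for marginal smooths (interactions use 5 x 5)
#' @return a `smooth_model`
#' @export
fit_ingestion_model <- function(trials, k = 8) {
  fit_gam(trials, "kj_ingested",
          list(smooth_term("hif", k = k),
               smooth_term("temperature", k = 6),
               smooth_term("pct_finfish", k = 6),
               smooth_term(c("hif", "temperature"), k = 5,
                           interaction_only = TRUE),
               smooth_term(c("hif", "pct_finfish"), k = 5,
                           interaction_only = TRUE)),
          response_units = "kJ")
}

#' Predict ingested energy, floored at zero
#'
#' @param model the ingestion `smooth_model`
#' @param hif,temperature,pct_finfish predictor vectors (recycled)
#' @param coefs optional coefficient draw
#' @return kJ ingested (>= 0)
#' @export
predict_ingestion <- function(model, hif, temperature, pct_finfish,
                              coefs = NULL) {
  nd <- data.frame(hif = hif, temperature = temperature,
                   pct_finfish = pct_finfish)
  pmax(0, as.numeric(predict(model, nd, coefs = coefs)))
}

#' Fit the full model chain
#'
#' Convenience wrapper fitting models 1a/1b (diel depth), 2 (movement
#' cost), 3 (HIF) and 4 (ingestion) from tag records, environmental fields
#' and laboratory tables.
#'
#' @param tags list of `tag_record`s
#' @param env an `env_field_set` (covariate source for models 1 and 3)
#' @param resp respirometry table
#' @param trials feeding-trial table
#' @param daily_hif optional precomputed daily HIF (see
#'   [assemble_hif_data()])
#' @return list with elements `depth_day`, `depth_night`, `cost`, `hif`,
#'   `ingestion` (all `smooth_model`s)
#' @export
fit_energetics_models <- function(tags, env, resp, trials,
                                  daily_hif = NULL) {
  dm <- fit_depth_models(assemble_depth_data(tags, env))
  list(depth_day = dm$day, depth_night = dm$night,
       cost = fit_cost_model(resp),
       hif = fit_hif_model(assemble_hif_data(tags, env, daily_hif)),
       ingestion = fit_ingestion_model(trials))
}
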