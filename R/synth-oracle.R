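#' Hand-composed generator-truth chain (noise-free oracle)
#'
#' Composes the synthetic generators' parametric truth surfaces directly —
#' diel depth from the depth link, ambient temperatures from the linear
#' profile, oxygen consumption from the respirometry surface, HIF from the
#' foraging link, ingestion from the feeding-trial surface, and the balance
#' from the accounting identity — per grid cell and month, without touching
#' any fitted model. With a noise-free configuration this is the analytic
#' value the fitted chain should reproduce; it exists so end-to-end tests
#' have an oracle that is independent of the fitting path.
#'
#' @param cfg the [synth_config()] whose parameter store defines truth
#' @param env an `env_field_set` generated from `cfg` (use a noise-free
#'   config for an exact oracle)
#' @param const an [energetics_constants()]
#' @param ref reference [fish_state()]
#' @param months months to evaluate
#' @return list per month: matrices `day_depth`, `night_depth`, `t_day`,
#'   `t_night`, `mo2_day`, `mo2_night`, `cost`, `hif`, `ingested`,
#'   `balance`, `day_length`, plus the input fields
#' @export
project_energetics_truth <- function(cfg, env,
                                     const = energetics_constants(),
                                     ref = NULL, months = NULL) {
  stopifnot(inherits(cfg, "synth_config"), inherits(env, "env_field_set"))
  if (is.null(ref)) ref <- fish_state(const$ref_length_cm,
                                      const$ref_weight_kg, const)
  if (is.null(months)) months <- env$months
  g <- env$grid
  dp <- cfg$depth; hp <- cfg$hif
  lat_mat <- outer(rep(1, g$n_lon), env$lat)
  lapply(months, function(m) {
    mid_date <- as.Date(sprintf("2005-%02d-15", ((m - 1) %% 12) + 1))
    sst <- env$fields$sst[, , m]
    t200 <- env$fields$t200[, , m]
    o2d <- env$fields$o2depth_3p5[, , m]
    zoo <- env$fields$mesozoo[, , m]
    daylen <- matrix(day_length_hours(as.vector(lat_mat), mid_date),
                     g$n_lon, g$n_lat)
    day_depth <- clamp(dp$day_d0 + dp$day_o2 * o2d +
                         dp$day_t200 * (t200 - 10), 0, 200)
    night_depth <- clamp(pmax(dp$night_d0 + dp$night_t200 * (t200 - 10), 0),
                         0, 200)
    t_day <- temp_at_depth(sst, t200, day_depth)
    t_night <- temp_at_depth(sst, t200, night_depth)
    mo2_day <- respirometry_truth(cfg, t_day, const$speed_day)
    mo2_night <- respirometry_truth(cfg, t_night, const$speed_night)
    cost <- mo2_to_kj(mo2_day, ref$weight_kg, daylen, const) +
      mo2_to_kj(mo2_night, ref$weight_kg, 24 - daylen, const)
    hif <- pmax(0, hp$h0 + hp$h_zoo * zoo + hp$h_daylen * daylen +
                  hp$h_length * ref$length_cm)
    ingested <- pmax(0, feeding_truth(cfg, hif, t_day, const$pct_finfish))
    balance <- daily_balance(ingested, cost, const)
    list(month = m, sst = sst, t200 = t200, o2depth_3p5 = o2d,
         mesozoo = zoo, day_length = daylen,
         day_depth = day_depth, night_depth = night_depth,
         t_day = t_day, t_night = t_night,
         mo2_day = mo2_day, mo2_night = mo2_night,
         cost = cost, hif = hif, ingested = ingested, balance = balance)
  })
}
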