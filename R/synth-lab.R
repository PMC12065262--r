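#' Generate a synthetic respirometry table
#'
#' Oxygen-consumption measurements over a temperature x swimming-speed
#' design, drawn from the parametric surface
#' `mo2 = b0 + b1 * speed^2 + b2 * exp(b3 * temperature)` plus Gaussian
#' noise — monotone increasing in both arguments over the sampled range,
#' mimicking captive-tuna swim-tunnel respirometry. The generating
#' parameters are recorded in the `"params"` attribute; recovery tests read
#' truth only from that store.
#'
#' @param cfg a [synth_config()]; see `cfg$respirometry` for the surface
#'   parameters, row count and sampled ranges, and `cfg$noise_sd$mo2`.
#' @return data.frame with columns `temperature` (degrees C), `speed`
#'   (body lengths s-1) and `mo2` (mg O2 kg-1 h-1), plus a `"params"`
#'   attribute.
#' @export
generate_respirometry <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  p <- cfg$respirometry
  with_seed(derive_seed(cfg$seed, "respirometry"), {
    temperature <- stats::runif(p$n, p$temp_range[1], p$temp_range[2])
    speed <- stats::runif(p$n, p$speed_range[1], p$speed_range[2])
    mo2 <- p$b0 + p$b1 * speed^2 + p$b2 * exp(p$b3 * temperature)
    if (cfg$noise_sd$mo2 > 0)
      mo2 <- mo2 + stats::rnorm(p$n, 0, cfg$noise_sd$mo2)
    out <- data.frame(temperature = temperature, speed = speed,
                      mo2 = pmax(mo2, 1))
    attr(out, "params") <- p
    out
  })
}

#' Evaluate the respirometry truth surface
#' @param cfg a [synth_config()]
#' @param temperature,speed predictor values
#' @return mo2 in mg O2 kg-1 h-1
#' @export
respirometry_truth <- function(cfg, temperature, speed) {
  p <- cfg$respirometry
  p$b0 + p$b1 * speed^2 + p$b2 * exp(p$b3 * temperature)
}

#' Generate a synthetic feeding-trial table
#'
#' Captive feeding trials linking the Heat Increment of Feeding to meal
#' energy: `kj = g0 * hif * (1 + g1 * (temperature - t0)) *
#' (1 + g2 * (pct_finfish - 70) / 100)` plus Gaussian noise, so energy
#' ingested is proportional to HIF, modulated by water temperature and diet
#' composition, and exactly zero at `hif = 0` in noise-free mode. Generating
#' parameters are stored in the `"params"` attribute.
#'
#' @param cfg a [synth_config()]; see `cfg$trials` and `cfg$noise_sd$kj`.
#' @return data.frame with columns `hif` (degree C hour), `temperature`
#'   (degrees C), `pct_finfish` (% in [0, 100]) and `kj_ingested` (kJ), plus
#'   a `"params"` attribute.
#' @export
generate_feeding_trials <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  p <- cfg$trials
  with_seed(derive_seed(cfg$seed, "trials"), {
    hif <- stats::runif(p$n, p$hif_range[1], p$hif_range[2])
    temperature <- stats::runif(p$n, p$temp_range[1], p$temp_range[2])
    pct <- stats::runif(p$n, p$pct_range[1], p$pct_range[2])
    kj <- feeding_truth(cfg, hif, temperature, pct)
    if (cfg$noise_sd$kj > 0) kj <- kj + stats::rnorm(p$n, 0, cfg$noise_sd$kj)
    out <- data.frame(hif = hif, temperature = temperature,
                      pct_finfish = pct, kj_ingested = pmax(kj, 0))
    attr(out, "params") <- p
    out
  })
}

#' Evaluate the feeding-trial truth surface
#' @param cfg a [synth_config()]
#' @param hif,temperature,pct_finfish predictor values
#' @return kJ ingested
#' @export
feeding_truth <- function(cfg, hif, temperature, pct_finfish) {
  p <- cfg$trials
  p$g0 * hif * (1 + p$g1 * (temperature - p$t0)) *
    (1 + p$g2 * (pct_finfish - 70) / 100)
}
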