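#' Fixed constants of the energetics accounting
#'
#' The conversion and accounting rules that close the daily energy budget:
#' the oxycalorific coefficient (13.59 J per mg O2), the fixed fractional
#' losses to specific dynamic action (9.2%) and excretion/egestion (27%),
#' the diel swimming-speed convention (2 BL s-1 by day, 1 BL s-1 by night),
#' the assumed diet (70% finfish), the reference fish (80 cm fork length,
#' 11 kg), the favorable thermal envelope (11-22 degrees C SST, inclusive),
#' and the hypoxia threshold defining the oxygen surface (3.5 ml L-1).
#' The length-weight relationship is allometric, `W = a * L^b`, with default
#' coefficients calibrated so that 80 cm maps to 11.0 kg.
#'
#' @param oxycal_j_per_mg J per mg O2
#' @param sda_loss,egestion_loss fractional losses applied to ingested energy
#' @param speed_day,speed_night swimming speeds, body lengths s-1
#' @param pct_finfish assumed percent finfish in diet
#' @param ref_length_cm,ref_weight_kg reference fish used for seascape maps
#' @param thermal_min,thermal_max favorable SST envelope, degrees C
#' @param o2_threshold_ml_l dissolved-oxygen threshold, ml L-1
#' @param lw_a,lw_b allometric length(cm)-weight(kg) coefficients
#' @return an object of class `energetics_constants`
#' @examples
#' const <- energetics_constants()
#' mo2_to_kj(100, 11, 24, const)
#' @export
energetics_constants <- function(oxycal_j_per_mg = 13.59,
                                 sda_loss = 0.092,
                                 egestion_loss = 0.27,
                                 speed_day = 2,
                                 speed_night = 1,
                                 pct_finfish = 70,
                                 ref_length_cm = 80,
                                 ref_weight_kg = 11,
                                 thermal_min = 11,
                                 thermal_max = 22,
                                 o2_threshold_ml_l = 3.5,
                                 lw_a = 11 / 80^3,
                                 lw_b = 3) {
  if (sda_loss < 0 || sda_loss >= 1 || egestion_loss < 0 || egestion_loss >= 1)
    stop("loss fractions must lie in [0, 1)", call. = FALSE)
  if (sda_loss + egestion_loss >= 1)
    stop("sda_loss + egestion_loss must be < 1", call. = FALSE)
  if (thermal_min >= thermal_max)
    stop("thermal_min must be < thermal_max", call. = FALSE)
  const <- list(oxycal_j_per_mg = oxycal_j_per_mg, sda_loss = sda_loss,
                egestion_loss = egestion_loss, speed_day = speed_day,
                speed_night = speed_night, pct_finfish = pct_finfish,
                ref_length_cm = ref_length_cm, ref_weight_kg = ref_weight_kg,
                thermal_min = thermal_min, thermal_max = thermal_max,
                o2_threshold_ml_l = o2_threshold_ml_l,
                lw_a = lw_a, lw_b = lw_b)
  w_ref <- lw_a * ref_length_cm^lw_b
  if (abs(w_ref - ref_weight_kg) / ref_weight_kg > 0.2)
    stop("length-weight coefficients inconsistent with the reference fish ",
         "(predicted ", round(w_ref, 2), " kg)", call. = FALSE)
  structure(const, class = "energetics_constants")
}

#' Reference fish state
#'
#' @param length_cm fork length, cm (> 0)
#' @param weight_kg weight, kg; defaults to the allometric prediction
#' @param const an [energetics_constants()]
#' @return a `fish_state` list with `length_cm` and `weight_kg`
#' @export
fish_state <- function(length_cm, weight_kg = NULL,
                       const = energetics_constants()) {
  if (length_cm <= 0) stop("length must be > 0", call. = FALSE)
  if (is.null(weight_kg)) weight_kg <- length_to_weight(length_cm, const)
  if (weight_kg <= 0) stop("weight must be > 0", call. = FALSE)
  w_lw <- length_to_weight(length_cm, const)
  if (abs(weight_kg - w_lw) / w_lw > 0.2)
    warning("weight deviates from the length-weight curve by more than 20%")
  structure(list(length_cm = length_cm, weight_kg = weight_kg),
            class = "fish_state")
}

#' Convert oxygen consumption to energy
#'
#' `kJ = MO2 (mg O2 kg-1 h-1) x weight (kg) x hours x oxycal (J/mg) / 1000`.
#'
#' @param mo2 mass-specific oxygen consumption, mg O2 kg-1 h-1 (>= 0)
#' @param weight_kg fish weight, kg (>= 0)
#' @param hours duration, h (>= 0)
#' @param const an [energetics_constants()]
#' @return energy in kJ
#' @examples
#' mo2_to_kj(1, 1, 1)   # 0.01359 kJ = 13.59 J
#' @export
mo2_to_kj <- function(mo2, weight_kg, hours, const = energetics_constants()) {
  if (any(mo2 < 0) || any(weight_kg < 0) || any(hours < 0))
    stop("mo2_to_kj: all arguments must be >= 0", call. = FALSE)
  mo2 * weight_kg * hours * const$oxycal_j_per_mg / 1000
}

#' Daily energy balance
#'
#' Ingested energy minus fixed fractional losses to specific dynamic action
#' and excretion/egestion, minus the metabolic cost of movement. May be
#' negative (energetic deficit).
#'
#' @param ingested_kj daily energy ingested, kJ (>= 0)
#' @param movement_cost_kj daily movement cost, kJ (>= 0)
#' @param const an [energetics_constants()]
#' @return balance in kJ
#' @examples
#' daily_balance(1000, 100)   # 1000 - 92 - 270 - 100 = 538
#' @export
daily_balance <- function(ingested_kj, movement_cost_kj,
                          const = energetics_constants()) {
  if (any(ingested_kj < 0) || any(movement_cost_kj < 0))
    stop("daily_balance: inputs must be >= 0", call. = FALSE)
  ingested_kj * (1 - const$sda_loss - const$egestion_loss) - movement_cost_kj
}

#' Allometric length-to-weight conversion
#'
#' @param length_cm fork length, cm (> 0)
#' @param const an [energetics_constants()] carrying `lw_a`, `lw_b`
#' @return weight in kg
#' @export
length_to_weight <- function(length_cm, const = energetics_constants()) {
  if (any(length_cm <= 0)) stop("length must be > 0", call. = FALSE)
  const$lw_a * length_cm^const$lw_b
}

#' Interpolate fork length within a deployment
#'
#' Linear growth between the recorded release and recapture lengths.
#'
#' @param release_length_cm,recapture_length_cm endpoint lengths, cm
#' @param release_date,recapture_date endpoint dates
#' @param date `Date` vector within the deployment
#' @return length in cm at `date`
#' @export
interpolate_length <- function(release_length_cm, recapture_length_cm,
                               release_date, recapture_date, date) {
  if (any(date < release_date) || any(date > recapture_date))
    stop("date outside deployment", call. = FALSE)
  span <- as.numeric(recapture_date - release_date)
  f <- if (span == 0) 0 else as.numeric(date - release_date) / span
  release_length_cm + f * (recapture_length_cm - release_length_cm)
}
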