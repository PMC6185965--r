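#' Crop parameter sets for the generic switchable-stress model
#'
#' Two shipped presets: `"winter_wheat"` (C3; autumn sowing with a low base
#' temperature standing in for vernalization, heat threshold 31 degC) and
#' `"grain_maize"` (C4; spring sowing, heat threshold 35 degC, no CO2 response
#' of RUE or leaf area). Any field can be overridden through `...`.
#'
#' Fields: `crop_class` ("C3"/"C4"); `sow_doy` (calendar sowing day); `t_base`,
#' `t_opt`, `t_max` (degC cardinal temperatures; RUE follows a trapezoid between
#' `t_base` and `t_opt` and declines to zero at `t_max`); `tt_anth`, `tt_mat`
#' (thermal time from sowing to anthesis / maturity, degC d); `rue` (g MJ-1);
#' `hi` (harvest index); `k_ext` (light extinction); `max_lai`; `t_crit` (heat
#' threshold, degC); `heat_slope` (yield fraction lost per degC d above
#' threshold); `heat_window` (thermal-time span around anthesis, degC d, as
#' `c(before, after)`); `te_c` (transpiration-efficiency coefficient,
#' g kPa mm-1); `beta_rue`, `gamma_te`, `lambda_lai` (CO2 response
#' coefficients; `beta_rue = lambda_lai = 0` enforced for C4); `d_heat`,
#' `d_cool` (canopy-temperature offsets, degC); `kr` (daily extractable soil
#' water fraction); `senescence_threshold` (cumulative heat exceedance, degC d,
#' beyond which leaf-area growth stops; `Inf` disables); `max_days` (season
#' length cap).
#'
#' @param preset `"winter_wheat"` or `"grain_maize"`.
#' @param ... named overrides of any field.
#' @return a validated `crop_parameters` list.
#' @export
crop_parameters <- function(preset = c("winter_wheat", "grain_maize"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    winter_wheat = list(
      crop = "winter_wheat", crop_class = "C3", sow_doy = 289L,
      t_base = 0, t_opt = 24, t_max = 35, tt_anth = 1150, tt_mat = 1800,
      rue = 3.0, hi = 0.45, k_ext = 0.6, max_lai = 6,
      t_crit = 31, heat_slope = 0.04, heat_window = c(100, 150),
      te_c = 5.0, beta_rue = 0.20, gamma_te = 0.35, lambda_lai = 0.06,
      d_heat = 5, d_cool = 2, kr = 0.1,
      senescence_threshold = Inf, max_days = 330L
    ),
    grain_maize = list(
      crop = "grain_maize", crop_class = "C4", sow_doy = 115L,
      t_base = 8, t_opt = 30, t_max = 42, tt_anth = 600, tt_mat = 1150,
      rue = 3.6, hi = 0.50, k_ext = 0.65, max_lai = 5,
      t_crit = 35, heat_slope = 0.05, heat_window = c(80, 120),
      te_c = 9.0, beta_rue = 0, gamma_te = 0.25, lambda_lai = 0,
      d_heat = 5, d_cool = 2, kr = 0.1,
      senescence_threshold = Inf, max_days = 240L
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) {
    abort(paste("unknown crop parameter(s):", paste(unknown, collapse = ", ")))
  }
  p[names(dots)] <- dots
  validate_crop_parameters(p)
}

validate_crop_parameters <- function(p) {
  if (!p$crop_class %in% c("C3", "C4")) abort("crop_class must be 'C3' or 'C4'")
  if (!(p$t_base < p$t_opt && p$t_opt < p$t_max)) {
    abort("cardinal temperatures must satisfy t_base < t_opt < t_max")
  }
  if (!(p$tt_anth < p$tt_mat)) abort("thermal time to anthesis must precede maturity")
  for (f in c("rue", "hi", "te_c", "k_ext", "max_lai", "kr")) {
    if (p[[f]] <= 0) abort(sprintf("`%s` must be positive", f))
  }
  if (p$hi > 1) abort("harvest index must be <= 1")
  if (p$kr > 1) abort("`kr` must be <= 1")
  if (p$heat_slope < 0) abort("`heat_slope` must be non-negative")
  if (p$d_heat < 0 || p$d_cool < 0) abort("canopy offsets must be non-negative")
  if (length(p$heat_window) != 2 || any(p$heat_window < 0)) {
    abort("`heat_window` must be c(before, after) in degC d, non-negative")
  }
  if (p$crop_class == "C4" && (p$beta_rue != 0 || p$lambda_lai != 0)) {
    abort("C4 crops must have beta_rue = 0 and lambda_lai = 0")
  }
  structure(p, class = "crop_parameters")
}

#' The six canonical stress treatments
#'
#' T1 potential (no water limitation, no heat); T2 heat via air temperature,
#' irrigated; T3 heat via canopy temperature, irrigated; T4 water-limited, no
#' heat; T5 water-limited with air-temperature heat; T6 water-limited with
#' canopy-temperature heat.
#'
#' @return tibble `(treatment, water_limited, heat_mode)`.
#' @export
treatments <- function() {
  tibble::tibble(
    treatment = paste0("T", 1:6),
    water_limited = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    heat_mode = c("none", "air", "canopy", "none", "air", "canopy")
  )
}

#' Saturation vapor pressure (Tetens)
#'
#' `es(t) = 0.6108 * exp(17.27 t / (t + 237.3))` kPa; strictly increasing and
#' convex over the physiological range, which is what makes atmospheric water
#' demand respond non-linearly to warming.
#'
#' @param t air temperature (degC), > -50; vectorized.
#' @return saturation vapor pressure (kPa).
#' @export
saturation_vapor_pressure <- function(t) {
  if (any(t <= -50)) abort("temperature out of the valid Tetens range")
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Daily mean vapor pressure deficit
#'
#' `VPD = max(0, (es(tmax) + es(tmin))/2 - ea)`.
#'
#' @param tmax,tmin daily extreme temperatures (degC), `tmin <= tmax`.
#' @param ea actual vapor pressure (kPa), >= 0.
#' @return VPD (kPa); vectorized.
#' @export
daily_vpd <- function(tmax, tmin, ea) {
  if (any(tmin > tmax)) abort("`tmin` must not exceed `tmax`")
  if (any(ea < 0)) abort("`ea` must be non-negative")
  pmax(0, (saturation_vapor_pressure(tmax) + saturation_vapor_pressure(tmin)) / 2 - ea)
}

#' Daily thermal time increment
#'
#' Linear between base and optimum, zero below base, capped at
#' `t_opt - t_base` above the optimum.
#'
#' @param tavg daily mean temperature (degC).
#' @param t_base,t_opt cardinal temperatures, `t_base < t_opt`.
#' @return increment (degC d); vectorized.
#' @export
thermal_time_increment <- function(tavg, t_base, t_opt) {
  if (any(t_base >= t_opt)) abort("`t_base` must be below `t_opt`")
  clamp(tavg, t_base, t_opt) - t_base
}

#' Canopy temperature from air temperature and water status
#'
#' `T_c = t_air + d_heat * (1 - f_w) - d_cool * f_w`: a fully transpiring crop
#' (`f_w = 1`) is cooler than the air by `d_cool`; a fully stressed crop
#' (`f_w = 0`) is warmer by `d_heat`. Strictly decreasing in `f_w`.
#'
#' @param t_air air temperature (degC).
#' @param f_w water-stress factor in `[0, 1]` (1 = unstressed).
#' @param d_heat,d_cool non-negative canopy offsets (degC).
#' @return canopy temperature (degC); vectorized.
#' @export
canopy_temperature <- function(t_air, f_w, d_heat = 5, d_cool = 2) {
  if (any(f_w < 0 | f_w > 1)) abort("`f_w` must lie in [0, 1]")
  if (any(d_heat < 0) || any(d_cool < 0)) abort("canopy offsets must be non-negative")
  t_air + d_heat * (1 - f_w) - d_cool * f_w
}

#' Harvest-index retention after reproductive heat stress
#'
#' `max(0, 1 - slope * sum(max(0, T_d - t_crit)))` over the driver temperatures
#' inside the heat-sensitive window; 1 when the threshold is never exceeded,
#' floored at 0.
#'
#' @param temps driver temperatures (degC) within the sensitive window.
#' @param t_crit critical threshold (degC).
#' @param slope fraction of yield lost per degC d of exceedance, >= 0.
#' @return retention factor in `[0, 1]`.
#' @export
heat_stress_retention <- function(temps, t_crit, slope) {
  if (any(slope < 0)) abort("`slope` must be non-negative")
  max(0, 1 - slope * sum(pmax(0, temps - t_crit)))
}

#' CO2 response multipliers
#'
#' Logarithmic responses relative to the 360 ppm ambient reference:
#' `te_mult = 1 + gamma_te * ln(co2/360)` for both classes;
#' `rue_mult = 1 + beta_rue * ln(co2/360)` and
#' `lai_mult = 1 + lambda_lai * ln(co2/360)` for C3 crops, exactly 1 for C4
#' (elevated CO2 leaves C4 potential yields untouched and acts only through
#' transpiration efficiency).
#'
#' @param crop_class `"C3"` or `"C4"`.
#' @param co2 concentration (ppm), >= 360; vectorized.
#' @param params a [crop_parameters()] supplying the coefficients, or `NULL`
#'   with coefficients passed explicitly.
#' @param beta_rue,gamma_te,lambda_lai coefficients used when `params` is NULL.
#' @return tibble `(rue_mult, te_mult, lai_mult)`.
#' @export
co2_factors <- function(crop_class, co2, params = NULL,
                        beta_rue = 0, gamma_te = 0.2, lambda_lai = 0) {
  if (any(co2 < 360)) abort("`co2` below the 360 ppm ambient reference")
  if (!crop_class %in% c("C3", "C4")) abort("crop_class must be 'C3' or 'C4'")
  if (!is.null(params)) {
    beta_rue <- params$beta_rue
    gamma_te <- params$gamma_te
    lambda_lai <- params$lambda_lai
  }
  l <- log(co2 / 360)
  c3 <- crop_class == "C3"
  tibble::tibble(
    rue_mult = if (c3) 1 + beta_rue * l else rep(1, length(l)),
    te_mult = 1 + gamma_te * l,
    lai_mult = if (c3) 1 + lambda_lai * l else rep(1, length(l))
  )
}

#' Crop water demand from potential growth and VPD
#'
#' `demand = potential_growth * vpd / (te_c * te_mult)` (mm): linear in VPD and
#' in potential growth, and strictly decreasing in the CO2
#' transpiration-efficiency multiplier.
#'
#' @param potential_growth unstressed biomass increment (g m-2 d-1), >= 0.
#' @param vpd vapor pressure deficit (kPa), >= 0.
#' @param te_c transpiration-efficiency coefficient (g kPa mm-1), > 0.
#' @param te_mult CO2 multiplier on TE, > 0.
#' @return transpiration demand (mm d-1); vectorized.
#' @export
transpiration_demand <- function(potential_growth, vpd, te_c, te_mult = 1) {
  if (any(te_c <= 0)) abort("`te_c` must be positive")
  if (any(potential_growth < 0) || any(vpd < 0) || any(te_mult <= 0)) {
    abort("inputs must be non-negative (te_mult positive)")
  }
  potential_growth * vpd / (te_c * te_mult)
}

#' One daily step of the soil-water bucket
#'
#' The soil can release at most the fraction `kr` of its current store per day.
#' With irrigation on, applied water tops the supply up to demand so the crop is
#' never stressed (`f_w = 1`); irrigation water is consumed the same day and
#' does not enter the store. Rain above the store capacity drains. Water is
#' conserved exactly: `precip - soil_uptake - drainage = state_new - state`
#' (irrigation enters and leaves in the same step).
#'
#' @param state soil water (mm), in `[0, tawc]`.
#' @param precip rainfall (mm), >= 0.
#' @param demand transpiration demand (mm), >= 0.
#' @param tawc bucket capacity (mm).
#' @param irrigation logical: full automatic irrigation on/off.
#' @param kr daily extractable fraction of the store, in `(0, 1]`.
#' @return tibble `(state, supply, f_w, irrigation, drainage)` where `supply`
#'   is total water transpired (soil + irrigation); all vectorized.
#' @export
water_balance_step <- function(state, precip, demand, tawc, irrigation = FALSE,
                               kr = 0.1) {
  if (any(demand < 0)) abort("`demand` must be non-negative")
  if (any(state < -1e-9) || any(state > tawc + 1e-9)) {
    abort("`state` must lie in [0, tawc]")
  }
  if (any(precip < 0)) abort("`precip` must be non-negative")
  soil_supply <- pmin(demand, kr * state)
  irr <- ifelse(irrigation, pmax(demand - soil_supply, 0), 0)
  supply <- soil_supply + irr
  f_w <- clamp(ifelse(demand == 0, 1, supply / demand), 0, 1)
  # full automatic irrigation removes stress exactly (not merely up to rounding)
  f_w <- ifelse(rep_len(irrigation, length(f_w)), 1, f_w)
  pre <- state + precip - soil_supply
  new_state <- clamp(pre, 0, tawc)
  drainage <- pmax(pre - tawc, 0)
  tibble::tibble(state = new_state, supply = supply, f_w = f_w,
                 irrigation = irr, drainage = drainage)
}
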