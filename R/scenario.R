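#' Define a delta-change climate scenario
#'
#' A scenario perturbs a baseline daily series with monthly mean-temperature
#' offsets and monthly precipitation factors, optionally flips the wet/dry state
#' of selected days, and carries the CO2 concentration of its forcing pathway.
#' Higher-moment variability changes are out of scope; wet/dry flips are taken as
#' explicit plans or rates rather than inferred from climate-model output.
#'
#' @param id scenario identifier; `"baseline"` must have zero offsets, unit
#'   factors and 360 ppm CO2.
#' @param dtemp twelve monthly temperature offsets (degC), applied to
#'   tmin/tavg/tmax alike.
#' @param pfact twelve monthly precipitation factors (unitless, >= 0).
#' @param co2 CO2 concentration (ppm).
#' @param flip_wet_to_dry,flip_dry_to_wet fractions of baseline wet (dry) days to
#'   flip to dry (wet) when a flip plan is materialized with [make_flip_plan()].
#' @param rain_shape,rain_mean gamma parameters for rainfall drawn onto
#'   dry-to-wet flipped days.
#' @return a `scenario_deltas` list.
#' @export
scenario_deltas <- function(id, dtemp = rep(0, 12), pfact = rep(1, 12), co2 = 360,
                            flip_wet_to_dry = 0, flip_dry_to_wet = 0,
                            rain_shape = 0.8, rain_mean = 4.5) {
  if (length(dtemp) != 12 || length(pfact) != 12) {
    abort("`dtemp` and `pfact` must have one value per month")
  }
  if (any(pfact < 0)) abort("precipitation factors must be non-negative")
  assert_scalar_number(co2, "co2", lo = 1)
  assert_scalar_number(flip_wet_to_dry, "flip_wet_to_dry", lo = 0, hi = 1)
  assert_scalar_number(flip_dry_to_wet, "flip_dry_to_wet", lo = 0, hi = 1)
  if (identical(id, "baseline") &&
      (any(dtemp != 0) || any(pfact != 1) || co2 != 360 ||
       flip_wet_to_dry != 0 || flip_dry_to_wet != 0)) {
    abort("the baseline scenario must have zero offsets, unit factors and 360 ppm CO2")
  }
  structure(
    list(id = id, dtemp = as.numeric(dtemp), pfact = as.numeric(pfact),
         co2 = co2, flip_wet_to_dry = flip_wet_to_dry,
         flip_dry_to_wet = flip_dry_to_wet,
         rain_shape = rain_shape, rain_mean = rain_mean),
    class = "scenario_deltas"
  )
}

#' @rdname scenario_deltas
#' @export
baseline_scenario <- function() scenario_deltas("baseline")

#' Preset RCP x climate-model-analogue scenario deltas
#'
#' Stylized pathway analogues: mean warming grows with forcing (RCP2.6 < 4.5 <
#' 8.5, with extra summer warming), CO2 follows the study's pathway levels
#' (442 / 499 / 571 ppm vs 360 ppm ambient), and two climate-model analogues
#' bracket the precipitation response: `"warm-wet"` (milder warming, wetter) and
#' `"hot-dry"` (stronger warming, drier summers with wet days flipped dry).
#'
#' @param rcp one of `"rcp26"`, `"rcp45"`, `"rcp85"`.
#' @param gcm one of `"warm-wet"`, `"hot-dry"`.
#' @return a [scenario_deltas()].
#' @export
rcp_analogue <- function(rcp = c("rcp45", "rcp26", "rcp85"),
                         gcm = c("hot-dry", "warm-wet")) {
  rcp <- match.arg(rcp)
  gcm <- match.arg(gcm)
  base_dt <- switch(rcp, rcp26 = 1.0, rcp45 = 1.8, rcp85 = 3.2)
  co2 <- switch(rcp, rcp26 = 442, rcp45 = 499, rcp85 = 571)
  summer <- c(0, 0, 0, 0.2, 0.5, 1, 1, 1, 0.5, 0.2, 0, 0) # extra summer warming
  if (gcm == "warm-wet") {
    dtemp <- base_dt * 0.85 + 0.6 * summer
    pfact <- 1 + c(rep(0.08, 3), rep(0.03, 6), rep(0.08, 3))
    f_wd <- 0
    f_dw <- 0.03
  } else {
    dtemp <- base_dt * 1.15 + 1.0 * summer
    pfact <- 1 - summer * 0.3
    f_wd <- 0.10
    f_dw <- 0
  }
  scenario_deltas(id = rcp, dtemp = dtemp, pfact = pfact, co2 = co2,
                  flip_wet_to_dry = f_wd, flip_dry_to_wet = f_dw)
}

#' Materialize a wet/dry flip plan against a baseline series
#'
#' Samples the configured fractions of baseline wet days to become dry and of
#' baseline dry days to become wet (with a gamma-drawn rainfall amount), giving
#' an explicit, reproducible per-day plan.
#'
#' @param weather baseline weather series (see [generate_weather()]).
#' @param deltas a [scenario_deltas()] carrying flip rates.
#' @param seed integer seed.
#' @return a tibble `(year, doy, direction, amount)`; `direction` is
#'   `"wet_to_dry"` or `"dry_to_wet"`, `amount` is NA for wet-to-dry flips.
#' @export
make_flip_plan <- function(weather, deltas, seed) {
  stopifnot(inherits(deltas, "scenario_deltas"))
  assert_cols(weather, c("year", "doy", "precip"), "weather")
  with_seed(seed, {
    wet <- weather$precip >= 0.1
    pick <- function(idx, frac) {
      k <- round(length(idx) * frac)
      if (k == 0) integer(0) else sort(sample(idx, k))
    }
    wd <- pick(which(wet), deltas$flip_wet_to_dry)
    dw <- pick(which(!wet), deltas$flip_dry_to_wet)
    amounts <- if (length(dw)) {
      pmax(rgamma(length(dw), shape = deltas$rain_shape,
                  scale = deltas$rain_mean / deltas$rain_shape), 0.1)
    } else numeric(0)
    tibble::tibble(
      year = c(weather$year[wd], weather$year[dw]),
      doy = c(weather$doy[wd], weather$doy[dw]),
      direction = rep(c("wet_to_dry", "dry_to_wet"), c(length(wd), length(dw))),
      amount = c(rep(NA_real_, length(wd)), amounts)
    )
  })
}

#' Apply the delta-change perturbation to a baseline weather series
#'
#' Temperatures are shifted by the monthly offsets, precipitation is scaled by
#' the monthly factors, and flip-plan days change wet/dry state: a baseline-wet
#' day made dry gets zero precipitation and 10% more global radiation; a
#' baseline-dry day made wet receives its planned rainfall amount and 10% less
#' radiation. The baseline scenario (zero offsets, unit factors, no flips) is
#' the identity.
#'
#' @param weather baseline weather series.
#' @param deltas a [scenario_deltas()].
#' @param flips optional explicit flip plan (see [make_flip_plan()]); defaults
#'   to no flips.
#' @return the perturbed weather series (same shape as the input).
#' @export
apply_delta_change <- function(weather, deltas, flips = NULL) {
  stopifnot(inherits(deltas, "scenario_deltas"))
  assert_cols(weather, c("year", "doy", "tmin", "tavg", "tmax", "precip", "rad"),
              "weather")
  out <- weather
  month <- .month_of_doy[out$doy]
  out$tmin <- out$tmin + deltas$dtemp[month]
  out$tavg <- out$tavg + deltas$dtemp[month]
  out$tmax <- out$tmax + deltas$dtemp[month]
  wet_base <- weather$precip >= 0.1
  out$precip <- out$precip * deltas$pfact[month]

  if (!is.null(flips) && nrow(flips)) {
    assert_cols(flips, c("year", "doy", "direction", "amount"), "flips")
    key <- paste(weather$year, weather$doy)
    idx <- match(paste(flips$year, flips$doy), key)
    if (anyNA(idx)) abort("flip plan references dates outside the baseline series")
    wd <- flips$direction == "wet_to_dry"
    if (any(!wet_base[idx[wd]])) {
      abort("flip plan marks a baseline-dry day as wet_to_dry")
    }
    if (any(wet_base[idx[!wd]])) {
      abort("flip plan marks a baseline-wet day as dry_to_wet")
    }
    if (any(!wd & (!is.finite(flips$amount) | flips$amount < 0.1))) {
      abort("dry_to_wet flips need a rainfall amount >= 0.1 mm")
    }
    out$precip[idx[wd]] <- 0
    out$rad[idx[wd]] <- out$rad[idx[wd]] * 1.10
    out$precip[idx[!wd]] <- flips$amount[!wd]
    out$rad[idx[!wd]] <- out$rad[idx[!wd]] * 0.90
  }
  attr(out, "scenario") <- deltas$id
  out
}

#' Build the scenario table for a factorial run
#'
#' One row per (scenario, climate-model analogue): the baseline plus every
#' requested RCP-analogue x GCM-analogue combination. Unbalanced sets (an RCP
#' with fewer GCM-analogues) are allowed and handled downstream.
#'
#' @param rcps character vector of RCP-analogue ids.
#' @param gcms character vector of GCM-analogue ids, or a named list mapping each
#'   rcp to its available analogues.
#' @return a tibble `(scenario, gcm, co2, deltas)` with a list-column of
#'   [scenario_deltas()]; the baseline row has `gcm = "obs"`.
#' @export
scenario_set <- function(rcps = c("rcp45", "rcp85"),
                         gcms = c("warm-wet", "hot-dry")) {
  gcm_for <- function(rcp) if (is.list(gcms)) gcms[[rcp]] else gcms
  base_row <- tibble::tibble(scenario = "baseline", gcm = "obs", co2 = 360,
                             deltas = list(baseline_scenario()))
  if (!length(rcps)) return(base_row)
  rows <- purrr::map_dfr(rcps, function(rcp) {
    tibble::tibble(scenario = rcp, gcm = gcm_for(rcp))
  })
  rows$co2 <- purrr::map2_dbl(rows$scenario, rows$gcm,
                              ~ rcp_analogue(.x, .y)$co2)
  rows$deltas <- purrr::map2(rows$scenario, rows$gcm, ~ rcp_analogue(.x, .y))
  dplyr::bind_rows(base_row, rows)
}
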