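# Vectorized daily-timestep season engine.
#
# All seasons advance in lockstep through the daily loop; every state variable is
# a vector with one element per season. simulate_season() is the single-season
# wrapper around this engine, and run_factorial() feeds it the whole experiment
# at once, which is what keeps the full treatment factorial tractable in R.
#
# wx: list of [max_days x n_slices] matrices (tmin, tavg, tmax, precip, rad, ea)
# widx: season -> weather slice column
# par: list of per-season parameter vectors (see crop_parameters fields)
simulate_seasons <- function(wx, widx, tawc, water0, par, water_limited,
                             heat_mode, co2, crop_class) {
  n <- length(widx)
  max_days <- nrow(wx$tavg)
  stopifnot(length(water_limited) == n, length(heat_mode) == n, length(co2) == n)

  cf <- co2_factors(crop_class, co2, beta_rue = par$beta_rue,
                    gamma_te = par$gamma_te, lambda_lai = par$lambda_lai)

  tt <- numeric(n)
  water <- water0
  biomass <- numeric(n)
  hsum <- numeric(n)
  lai_cap <- rep(Inf, n)
  anth_day <- rep(NA_integer_, n)
  mat_day <- rep(NA_integer_, n)
  transp <- numeric(n)
  irr_tot <- numeric(n)
  drain_tot <- numeric(n)
  precip_in <- numeric(n)
  fw_sum <- numeric(n)
  days <- numeric(n)
  alive <- rep(TRUE, n)

  heat_on <- heat_mode != "none"
  canopy <- heat_mode == "canopy"
  irrigated <- !water_limited

  for (d in seq_len(max_days)) {
    if (!any(alive)) break
    tmin_d <- wx$tmin[d, widx]
    tavg_d <- wx$tavg[d, widx]
    tmax_d <- wx$tmax[d, widx]
    prec_d <- wx$precip[d, widx] * alive
    rad_d <- wx$rad[d, widx]
    ea_d <- wx$ea[d, widx]

    tt <- tt + thermal_time_increment(tavg_d, par$t_base, par$t_opt) * alive
    cross_anth <- alive & is.na(anth_day) & tt >= par$tt_anth
    anth_day[cross_anth] <- d

    # leaf area: thermal-time-driven rise to anthesis, linear senescence to
    # maturity; heat-triggered senescence caps further expansion
    lai <- par$max_lai * cf$lai_mult *
      pmin(tt / par$tt_anth, pmax((par$tt_mat - tt) / (par$tt_mat - par$tt_anth), 0))
    lai <- pmin(lai, lai_cap)
    fint <- 1 - exp(-par$k_ext * lai)

    f_temp <- pmin(
      clamp((tavg_d - par$t_base) / (par$t_opt - par$t_base), 0, 1),
      clamp((par$t_max - tavg_d) / (par$t_max - par$t_opt), 0, 1)
    )
    pot <- par$rue * cf$rue_mult * fint * rad_d * f_temp * alive
    vpd <- daily_vpd(tmax_d, tmin_d, ea_d)
    demand <- transpiration_demand(pot, vpd, par$te_c, cf$te_mult)

    wb <- water_balance_step(water, prec_d, demand, tawc,
                             irrigation = irrigated, kr = par$kr)
    water <- wb$state
    f_w <- wb$f_w

    biomass <- biomass + pot * f_w

    t_driver <- ifelse(canopy,
                       canopy_temperature(tmax_d, f_w, par$d_heat, par$d_cool),
                       tmax_d)
    in_window <- tt >= (par$tt_anth - par$heat_before) &
      tt <= (par$tt_anth + par$heat_after)
    hsum <- hsum + pmax(t_driver - par$t_crit, 0) * (heat_on & in_window & alive)
    trigger <- is.infinite(lai_cap) & hsum > par$senescence_threshold
    lai_cap[trigger] <- lai[trigger]

    transp <- transp + wb$supply * alive
    irr_tot <- irr_tot + wb$irrigation * alive
    drain_tot <- drain_tot + wb$drainage * alive
    precip_in <- precip_in + prec_d
    fw_sum <- fw_sum + f_w * alive
    days <- days + alive

    mature <- alive & tt >= par$tt_mat
    mat_day[mature] <- d
    alive[mature] <- FALSE
  }

  matured <- !is.na(mat_day)
  mat_day[!matured] <- max_days
  anth_day[is.na(anth_day)] <- mat_day[is.na(anth_day)]
  retention <- ifelse(heat_on, pmax(1 - par$heat_slope * hsum, 0), 1)

  tibble::tibble(
    yield = biomass * par$hi * retention * 0.01,   # g m-2 -> t ha-1
    biomass = biomass * 0.01,
    anthesis_day = anth_day, maturity_day = mat_day, matured = matured,
    transpiration = transp, irrigation = irr_tot, drainage = drain_tot,
    precip_in = precip_in,
    water_start = water0, water_end = water,
    fw_mean = ifelse(days > 0, fw_sum / days, 1),
    heat_sum = hsum, retention = retention
  )
}

# expand a crop_parameters object (or a list of them indexed by midx) into the
# per-season parameter vectors the engine consumes
expand_params <- function(members, midx) {
  grab <- function(field) vapply(members, function(m) m[[field]][1], numeric(1))[midx]
  list(
    t_base = grab("t_base"), t_opt = grab("t_opt"), t_max = grab("t_max"),
    tt_anth = grab("tt_anth"), tt_mat = grab("tt_mat"),
    rue = grab("rue"), hi = grab("hi"), k_ext = grab("k_ext"),
    max_lai = grab("max_lai"), t_crit = grab("t_crit"),
    heat_slope = grab("heat_slope"),
    heat_before = vapply(members, function(m) m$heat_window[1], numeric(1))[midx],
    heat_after = vapply(members, function(m) m$heat_window[2], numeric(1))[midx],
    te_c = grab("te_c"), beta_rue = grab("beta_rue"),
    gamma_te = grab("gamma_te"), lambda_lai = grab("lambda_lai"),
    d_heat = grab("d_heat"), d_cool = grab("d_cool"), kr = grab("kr"),
    senescence_threshold = grab("senescence_threshold")
  )
}

# slice a weather series into aligned [max_days x n_starts] matrices
weather_matrices <- function(weather, starts, max_days) {
  idx <- outer(0:(max_days - 1L), as.integer(starts), "+")
  if (max(idx) > nrow(weather)) {
    abort("weather slice shorter than the season window")
  }
  vars <- c("tmin", "tavg", "tmax", "precip", "rad", "ea")
  out <- lapply(vars, function(v) {
    m <- matrix(weather[[v]][idx], nrow = max_days)
    if (anyNA(m)) abort("weather contains missing values inside a season window")
    m
  })
  names(out) <- vars
  out
}

#' Simulate one crop season
#'
#' Runs the daily loop for a single (weather, soil, parameters, treatment, CO2)
#' combination: thermal time drives phenology and a rise/senescence leaf-area
#' curve, intercepted radiation times RUE (with a trapezoidal temperature
#' suitability) gives potential growth, the transpiration-efficiency relation
#' converts growth demand into water demand, the soil bucket supplies it
#' (topped up by irrigation when the treatment is not water limited), and heat
#' exceedance above the critical threshold inside the anthesis window reduces
#' the harvest index — with air or simulated canopy temperature as the driver,
#' per the treatment.
#'
#' @param weather a weather series covering the season: the first occurrence of
#'   the sowing day of year starts the season, and at least `max_days` further
#'   days must be present (supply two calendar years for autumn-sown crops).
#' @param soil a one-row data frame with a `tawc` column (see [soil_profile()]),
#'   or a single TAWC value in mm.
#' @param params a [crop_parameters()] object.
#' @param treatment a treatment id `"T1"`..`"T6"` or one row of [treatments()].
#' @param co2 CO2 concentration (ppm), >= 360.
#' @param raw_fraction readily-available-water fraction for the initial store.
#' @return a one-row tibble: treatment flags, `yield` and `biomass` (t ha-1),
#'   `anthesis_day`/`maturity_day` (days after sowing), `matured`, seasonal
#'   `transpiration`/`irrigation`/`drainage`/`precip_in` (mm), start and end
#'   soil water, mean drought factor `fw_mean`, cumulative `heat_sum` (degC d)
#'   and harvest-index `retention`.
#' @export
simulate_season <- function(weather, soil, params, treatment = "T4", co2 = 360,
                            raw_fraction = 0.5) {
  stopifnot(inherits(params, "crop_parameters"))
  trt <- treatment
  if (is.character(trt)) {
    trt <- dplyr::filter(treatments(), .data$treatment == !!trt)
    if (!nrow(trt)) abort("unknown treatment id")
  }
  assert_cols(weather, c("year", "doy", "tmin", "tavg", "tmax", "precip", "rad", "ea"),
              "weather")
  tawc <- if (is.data.frame(soil)) soil$tawc[1] else soil
  start <- which(weather$doy == params$sow_doy)[1]
  if (is.na(start)) abort("weather does not contain the sowing day of year")
  wx <- weather_matrices(weather, start, params$max_days)

  res <- simulate_seasons(
    wx, widx = 1L, tawc = tawc,
    water0 = initial_soil_water(tawc, raw_fraction),
    par = expand_params(list(params), 1L),
    water_limited = trt$water_limited,
    heat_mode = trt$heat_mode,
    co2 = co2, crop_class = params$crop_class
  )
  dplyr::bind_cols(
    tibble::tibble(crop = params$crop, treatment = trt$treatment,
                   water_limited = trt$water_limited,
                   heat_mode = trt$heat_mode, co2 = co2,
                   sowing_doy = params$sow_doy),
    res
  )
}
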