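#' Define a climate profile for the stochastic weather generator
#'
#' The generator uses a harmonic seasonal cycle with AR(1) day-to-day temperature
#' residuals, a Bernoulli-gamma rainfall process, a harmonic radiation cycle, and
#' humidity tied to the dewpoint-approximately-tmin assumption. This minimal form
#' was chosen because its annual means are known in closed form (the harmonic sums
#' to zero over whole 365-day years), which the test suite exploits.
#'
#' @param mean_temp annual mean of daily average temperature (degC).
#' @param amp amplitude of the seasonal temperature harmonic (degC).
#' @param temp_sd marginal standard deviation of day-to-day temperature residuals
#'   (degC); 0 gives the deterministic seasonal cycle.
#' @param temp_ar1 lag-1 autocorrelation of the temperature residuals, in `[0, 1)`.
#' @param dtr diurnal temperature range (degC); `tmin = tavg - dtr/2`,
#'   `tmax = tavg + dtr/2`. Must be >= 0 (negative would imply tmin > tmax).
#' @param p_wet wet-day probability; a single value or one per calendar month.
#' @param rain_shape,rain_mean gamma shape and mean (mm) of wet-day rainfall.
#' @param rad_mean,rad_amp,rad_sd mean, seasonal amplitude and daily sd of global
#'   radiation (MJ m-2 d-1).
#' @param rh_frac actual vapor pressure as a fraction of saturation vapor pressure
#'   at tmin (dewpoint ~ tmin), in `(0, 1]`; keeps VPD non-negative.
#' @param wind_mean,wind_sd mean and sd of 10-m wind speed (m s-1).
#' @param peak_doy day-of-year at which the temperature harmonic peaks.
#' @param wet_rad_factor multiplier applied to radiation on wet days (cloudiness).
#' @return a `climate_profile` list.
#' @export
climate_profile <- function(mean_temp = 10, amp = 8, temp_sd = 2.5, temp_ar1 = 0.6,
                            dtr = 9, p_wet = 0.35, rain_shape = 0.8, rain_mean = 4.5,
                            rad_mean = 12, rad_amp = 9, rad_sd = 2, rh_frac = 0.85,
                            wind_mean = 3, wind_sd = 1, peak_doy = 200,
                            wet_rad_factor = 0.9) {
  if (dtr < 0) abort("`dtr` < 0 would imply tmin > tmax")
  if (!length(p_wet) %in% c(1L, 12L) || any(p_wet < 0 | p_wet > 1)) {
    abort("`p_wet` must be one probability or twelve monthly probabilities")
  }
  assert_scalar_number(temp_sd, "temp_sd", lo = 0)
  assert_scalar_number(temp_ar1, "temp_ar1", lo = 0, hi = 0.999)
  assert_scalar_number(rain_shape, "rain_shape", lo = 1e-6)
  assert_scalar_number(rain_mean, "rain_mean", lo = 1e-6)
  assert_scalar_number(rh_frac, "rh_frac", lo = 1e-6, hi = 1)
  structure(
    list(mean_temp = mean_temp, amp = amp, temp_sd = temp_sd, temp_ar1 = temp_ar1,
         dtr = dtr, p_wet = p_wet, rain_shape = rain_shape, rain_mean = rain_mean,
         rad_mean = rad_mean, rad_amp = rad_amp, rad_sd = rad_sd, rh_frac = rh_frac,
         wind_mean = wind_mean, wind_sd = wind_sd, peak_doy = peak_doy,
         wet_rad_factor = wet_rad_factor),
    class = "climate_profile"
  )
}

#' Preset climate profiles by latitude band
#'
#' Three stylized European bands: a cool wet `"boreal"` profile, a `"temperate"`
#' mid-latitude profile, and a `"mediterranean"` profile with hot dry summers
#' (monthly wet-day probabilities dipping in June-August).
#'
#' @param band one of `"boreal"`, `"temperate"`, `"mediterranean"`.
#' @return a [climate_profile()].
#' @export
lat_band_profile <- function(band = c("temperate", "boreal", "mediterranean")) {
  band <- match.arg(band)
  switch(band,
    boreal = climate_profile(mean_temp = 6, amp = 10, temp_sd = 3, p_wet = 0.45,
                             rain_mean = 3.5, rad_mean = 10, rad_amp = 8.5),
    temperate = climate_profile(),
    mediterranean = climate_profile(
      mean_temp = 15, amp = 9, temp_sd = 2.2, dtr = 11,
      p_wet = c(0.35, 0.33, 0.3, 0.25, 0.18, 0.1, 0.06, 0.07, 0.15, 0.28, 0.35, 0.37),
      rain_mean = 6, rad_mean = 15, rad_amp = 9.5
    )
  )
}

#' Generate a daily weather series
#'
#' Pure function of `(profile, n_years, seed)`: identical arguments give a
#' bit-identical series. Years are synthetic 365-day years (no leap days), so the
#' series covers whole years with no gaps.
#'
#' @param profile a [climate_profile()].
#' @param n_years number of whole years to generate (>= 1).
#' @param seed integer seed (mandatory).
#' @param start_year first calendar year label.
#' @return a tibble with one row per day: `date`, `year`, `doy`, `tmin`, `tavg`,
#'   `tmax` (degC), `precip` (mm), `rad` (MJ m-2 d-1), `ea` (kPa), `wind10` (m s-1).
#' @export
generate_weather <- function(profile, n_years, seed, start_year = 2001L) {
  stopifnot(inherits(profile, "climate_profile"))
  if (!is.numeric(n_years) || length(n_years) != 1 || n_years < 1 ||
      n_years != round(n_years)) {
    abort("`n_years` must be a positive whole number")
  }
  assert_scalar_number(seed, "seed")
  n_years <- as.integer(n_years)
  n <- 365L * n_years
  doy <- rep.int(1:365, n_years)
  year <- rep(seq_len(n_years), each = 365L) - 1L + as.integer(start_year)
  month <- .month_of_doy[doy]

  with_seed(seed, {
    tclim <- profile$mean_temp +
      profile$amp * cos(2 * pi * (doy - profile$peak_doy) / 365)
    if (profile$temp_sd > 0) {
      innov_sd <- profile$temp_sd * sqrt(1 - profile$temp_ar1^2)
      resid <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), profile$temp_ar1,
                                        method = "recursive"))
    } else {
      resid <- numeric(n)
    }
    tavg <- tclim + resid
    tmin <- tavg - profile$dtr / 2
    tmax <- tavg + profile$dtr / 2

    p_wet <- if (length(profile$p_wet) == 12L) profile$p_wet[month] else
      rep(profile$p_wet, n)
    wet <- runif(n) < p_wet
    amounts <- rgamma(n, shape = profile$rain_shape,
                      scale = profile$rain_mean / profile$rain_shape)
    precip <- ifelse(wet, pmax(amounts, 0.1), 0) # wet day := precip >= 0.1 mm

    rad <- profile$rad_mean +
      profile$rad_amp * cos(2 * pi * (doy - profile$peak_doy) / 365) +
      rnorm(n, 0, profile$rad_sd)
    rad <- pmax(rad * ifelse(wet, profile$wet_rad_factor, 1), 0.5)

    ea <- profile$rh_frac * saturation_vapor_pressure(tmin)
    wind10 <- pmax(profile$wind_mean + rnorm(n, 0, profile$wind_sd), 0.1)

    out <- tibble::tibble(
      date = as.Date(sprintf("%d-01-01", year)) + (doy - 1L),
      year = year, doy = doy,
      tmin = tmin, tavg = tavg, tmax = tmax,
      precip = precip, rad = rad, ea = ea, wind10 = wind10
    )
    attr(out, "profile") <- profile
    attr(out, "seed") <- seed
    class(out) <- c("weather_series", class(out))
    out
  })
}

#' Convert 10-m wind speed to 2-m wind speed
#'
#' The FAO-56 logarithmic wind profile, `u2 = u10 * 4.87 / ln(67.8 * 10 - 5.42)`.
#'
#' @param u10 wind speed at 10 m (m s-1), non-negative; vectorized.
#' @return wind speed at 2 m (m s-1).
#' @export
wind_at_2m <- function(u10) {
  if (any(u10 < 0)) abort("`u10` must be non-negative")
  u10 * 4.87 / log(67.8 * 10 - 5.42)
}
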