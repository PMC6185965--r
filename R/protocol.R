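#' Specify a pseudo-ensemble of crop-model parameterizations
#'
#' The multi-model ensemble is emulated by multiplicative parameter perturbation
#' of one generic model: member 1 is the unperturbed base, further members
#' jitter RUE, the transpiration-efficiency coefficient, the thermal-time
#' requirements (a shared factor for anthesis and maturity, preserving their
#' order), the heat-damage slope, and the CO2-response coefficients. The three
#' CO2 coefficients share a single factor per member so their relative sizes —
#' which keep water-limited yields non-decreasing in CO2 — are preserved.
#'
#' @param n_models number of members (>= 1).
#' @param seed integer seed.
#' @param sd_rue,sd_te,sd_tt,sd_heat_slope,sd_co2 standard deviations of the
#'   log-normal multiplicative jitters (0 disables a jitter).
#' @param canopy_capable logical: which members simulate canopy temperature;
#'   scalar or length `n_models`.
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_models = 4, seed = 1, sd_rue = 0.06, sd_te = 0.06,
                          sd_tt = 0.04, sd_heat_slope = 0.15, sd_co2 = 0.10,
                          canopy_capable = TRUE) {
  if (n_models < 1 || n_models != round(n_models)) {
    abort("`n_models` must be a positive whole number")
  }
  for (s in c(sd_rue, sd_te, sd_tt, sd_heat_slope, sd_co2)) {
    if (s < 0) abort("jitter standard deviations must be non-negative")
  }
  structure(
    list(n_models = as.integer(n_models), seed = seed, sd_rue = sd_rue,
         sd_te = sd_te, sd_tt = sd_tt, sd_heat_slope = sd_heat_slope,
         sd_co2 = sd_co2,
         canopy_capable = rep_len(canopy_capable, n_models)),
    class = "ensemble_spec"
  )
}

#' Build the pseudo-model ensemble
#'
#' @param base a [crop_parameters()] object.
#' @param spec an [ensemble_spec()].
#' @return a named list (`m1`, `m2`, ...) of validated [crop_parameters()];
#'   `m1` is `base` unchanged. The `"canopy"` attribute is a tibble
#'   `(model, canopy_capable)`. Deterministic under `spec$seed`; draws that
#'   violate the parameter invariants are rejected and redrawn.
#' @export
make_ensemble <- function(base, spec) {
  stopifnot(inherits(base, "crop_parameters"), inherits(spec, "ensemble_spec"))
  members <- vector("list", spec$n_models)
  members[[1]] <- base
  if (spec$n_models > 1) {
    with_seed(mix_seed(spec$seed, "ensemble", base$crop), {
      for (i in 2:spec$n_models) {
        for (try in 1:100) {
          p <- unclass(base)
          f <- function(sd) exp(rnorm(1, 0, sd))
          p$rue <- p$rue * f(spec$sd_rue)
          p$te_c <- p$te_c * f(spec$sd_te)
          tt_f <- f(spec$sd_tt)
          p$tt_anth <- p$tt_anth * tt_f
          p$tt_mat <- p$tt_mat * tt_f
          p$heat_slope <- p$heat_slope * f(spec$sd_heat_slope)
          co2_f <- f(spec$sd_co2)
          p$beta_rue <- p$beta_rue * co2_f
          p$gamma_te <- p$gamma_te * co2_f
          p$lambda_lai <- p$lambda_lai * co2_f
          ok <- tryCatch({
            members[[i]] <- validate_crop_parameters(p)
            TRUE
          }, error = function(e) FALSE)
          if (ok) break
          if (try == 100) abort("could not draw a valid ensemble member")
        }
      }
    })
  }
  names(members) <- paste0("m", seq_len(spec$n_models))
  attr(members, "canopy") <- tibble::tibble(
    model = names(members), canopy_capable = spec$canopy_capable
  )
  members
}

#' Run the full simulation factorial
#'
#' Executes the complete crossing cell x year x scenario/GCM-analogue x
#' pseudo-model x treatment (T1..T6) x CO2 arm for each crop on the grid. Every
#' scenario is run twice: once with ambient CO2 fixed at 360 ppm and once at the
#' scenario's elevated concentration. Weather is generated per (cell, scenario)
#' from the cell's latitude-band profile, perturbed by the scenario deltas with
#' a per-cell flip plan; two pad years are generated so autumn-sown seasons and
#' the final harvest year have complete windows. Rows are mutually independent
#' and the whole table is a pure function of the inputs and `seed`.
#'
#' @param grid a `crop_grid` from [generate_grid()].
#' @param scenarios a scenario table from [scenario_set()].
#' @param ensembles named list: crop name -> ensemble from [make_ensemble()].
#' @param n_years years per scenario period (harvest years `1..n_years`).
#' @param seed integer base seed.
#' @param raw_fraction readily-available-water fraction for initial soil water.
#' @return a `factorial_table` tibble keyed by `(crop, cell_id, year, scenario,
#'   gcm, model, treatment, co2_arm)` with season diagnostics; the crossing is
#'   complete (validated before return).
#' @export
run_factorial <- function(grid, scenarios, ensembles, n_years = 30, seed = 1,
                          raw_fraction = 0.5) {
  assert_cols(grid, c("cell_id", "region", "lat_band", "tawc", "crop"), "grid")
  assert_cols(scenarios, c("scenario", "gcm", "co2", "deltas"), "scenarios")
  if (anyDuplicated(scenarios[c("scenario", "gcm")])) {
    abort("duplicate (scenario, gcm) rows")
  }
  missing_ens <- setdiff(unique(grid$crop), names(ensembles))
  if (length(missing_ens)) {
    abort(paste("no ensemble supplied for crop(s):",
                paste(missing_ens, collapse = ", ")))
  }
  n_years <- as.integer(n_years)
  cells <- dplyr::distinct(grid, .data$cell_id, .data$region, .data$lat_band,
                           .data$tawc)
  n_pad_years <- n_years + 2L

  # weather per (cell, scenario-row), shared across crops
  wset <- vector("list", nrow(cells) * nrow(scenarios))
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    profile <- lat_band_profile(cells$lat_band[ci])
    base_wx <- generate_weather(profile, n_pad_years,
                                seed = mix_seed(seed, "wx", cells$cell_id[ci]))
    for (si in seq_len(nrow(scenarios))) {
      deltas <- scenarios$deltas[[si]]
      flips <- make_flip_plan(
        base_wx, deltas,
        seed = mix_seed(seed, "flip", cells$cell_id[ci],
                        scenarios$scenario[si], scenarios$gcm[si])
      )
      k <- k + 1L
      wset[[k]] <- apply_delta_change(base_wx, deltas, flips)
    }
  }
  wkey <- tidyr::crossing(ci = seq_len(nrow(cells)), si = seq_len(nrow(scenarios)))
  wkey <- dplyr::arrange(wkey, .data$ci, .data$si) # matches fill order above
  wkey$w <- seq_len(nrow(wkey))

  out <- vector("list", 0)
  for (crop_name in unique(grid$crop)) {
    members <- ensembles[[crop_name]]
    base <- members[[1]]
    max_days <- base$max_days
    # harvest year i: autumn-sown crops start in pad-year i, spring-sown in i+1
    year_offset <- if (base$sow_doy >= 244L) 0L else 1L
    starts <- (seq_len(n_years) - 1L + year_offset) * 365L + base$sow_doy

    n_slices <- nrow(wkey) * n_years
    wx <- list()
    for (v in c("tmin", "tavg", "tmax", "precip", "rad", "ea")) {
      wx[[v]] <- matrix(NA_real_, nrow = max_days, ncol = n_slices)
    }
    for (j in seq_len(nrow(wkey))) {
      m <- weather_matrices(wset[[wkey$w[j]]], starts, max_days)
      cols <- (j - 1L) * n_years + seq_len(n_years)
      for (v in names(m)) wx[[v]][, cols] <- m[[v]]
    }

    seasons <- tidyr::crossing(
      dplyr::mutate(wkey, slice0 = (dplyr::row_number() - 1L) * n_years),
      year = seq_len(n_years),
      model = names(members),
      treatment = treatments()$treatment,
      co2_arm = c("ambient", "elevated")
    )
    seasons <- dplyr::left_join(seasons, treatments(), by = "treatment")
    seasons$widx <- seasons$slice0 + seasons$year
    seasons$co2 <- ifelse(seasons$co2_arm == "ambient", 360,
                          scenarios$co2[seasons$si])
    midx <- match(seasons$model, names(members))

    cell_tawc <- cells$tawc[seasons$ci]
    res <- simulate_seasons(
      wx, widx = seasons$widx, tawc = cell_tawc,
      water0 = initial_soil_water(cell_tawc, raw_fraction),
      par = expand_params(members, midx),
      water_limited = seasons$water_limited,
      heat_mode = seasons$heat_mode,
      co2 = seasons$co2, crop_class = base$crop_class
    )
    out[[crop_name]] <- dplyr::bind_cols(
      tibble::tibble(
        crop = crop_name,
        cell_id = cells$cell_id[seasons$ci],
        region = cells$region[seasons$ci],
        year = seasons$year,
        scenario = scenarios$scenario[seasons$si],
        gcm = scenarios$gcm[seasons$si],
        model = seasons$model,
        treatment = seasons$treatment,
        water_limited = seasons$water_limited,
        heat_mode = seasons$heat_mode,
        co2_arm = seasons$co2_arm,
        co2 = seasons$co2
      ),
      res
    )
  }
  out <- dplyr::bind_rows(out)

  keys <- c("crop", "cell_id", "year", "scenario", "gcm", "model", "treatment",
            "co2_arm")
  expected <- sum(vapply(unique(grid$crop),
                         function(cr) length(ensembles[[cr]]), numeric(1))) *
    nrow(cells) * n_years * nrow(scenarios) * 6L * 2L
  counts <- dplyr::count(out, dplyr::across(dplyr::all_of(keys)))
  if (any(counts$n != 1L) || nrow(out) != expected) {
    abort("factorial crossing is incomplete or duplicated")
  }
  class(out) <- c("factorial_table", class(out))
  out
}

#' Seasonal crop water use summary
#'
#' Mean seasonal water use (transpiration, including any irrigation water
#' consumed) per cell, scenario, model, treatment and CO2 arm.
#'
#' @param table a factorial table from [run_factorial()].
#' @return a tibble with `mean_water_use` and `mean_irrigation` (mm).
#' @export
seasonal_water_use <- function(table) {
  if (!nrow(table)) abort("empty factorial table")
  assert_cols(table, c("crop", "cell_id", "scenario", "gcm", "model",
                       "treatment", "co2_arm", "transpiration", "irrigation"),
              "table")
  dplyr::summarise(
    dplyr::group_by(table, .data$crop, .data$cell_id, .data$scenario, .data$gcm,
                    .data$model, .data$treatment, .data$co2_arm),
    mean_water_use = mean(.data$transpiration),
    mean_irrigation = mean(.data$irrigation),
    .groups = "drop"
  )
}
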