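# shared fixture builders; everything is generated in code under fixed seeds

fixture_grid <- function(n_cells = 4, seed = 101,
                         regions = c("west", "east"),
                         lat_band = c("temperate", "mediterranean"),
                         crops = c("winter_wheat", "grain_maize"), ...) {
  generate_grid(n_cells, seed,
                region_plan(regions, lat_band = lat_band, crops = crops, ...))
}

fixture_ensembles <- function(crops = c("winter_wheat", "grain_maize"),
                              n_models = 2, seed = 77, ...) {
  lapply(stats::setNames(crops, crops), function(cr) {
    make_ensemble(crop_parameters(cr), ensemble_spec(n_models, seed = seed, ...))
  })
}

fixture_factorial <- function(n_cells = 4, n_years = 5, seed = 11,
                              crops = "grain_maize", n_models = 2,
                              rcps = "rcp85", gcms = "hot-dry", ...) {
  grid <- fixture_grid(n_cells, crops = crops, ...)
  scen <- scenario_set(rcps = rcps, gcms = gcms)
  ens <- fixture_ensembles(crops, n_models = n_models)
  list(grid = grid, scenarios = scen, ensembles = ens,
       table = run_factorial(grid, scen, ens, n_years = n_years, seed = seed))
}

# two years of weather with a deterministic profile, handy for season tests
fixture_weather <- function(n_years = 2, seed = 5, band = "temperate") {
  generate_weather(lat_band_profile(band), n_years, seed = seed)
}
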