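test_that("saturation vapor pressure is the Tetens form, increasing and convex", {
  expect_equal(saturation_vapor_pressure(0), 0.6108)
  # independent hand evaluation at 20 degC
  expect_equal(saturation_vapor_pressure(20), 2.3389, tolerance = 1e-3)
  es <- saturation_vapor_pressure
  expect_gt(es(30) - es(25), es(15) - es(10)) # convexity: demand grows faster when warm
  expect_error(es(-60), "range")
})

test_that("daily VPD behaves at saturation, dryness, and under warming", {
  es <- saturation_vapor_pressure
  expect_equal(daily_vpd(25, 15, (es(25) + es(15)) / 2), 0)
  expect_equal(daily_vpd(20, 20, 0), es(20))
  expect_gt(daily_vpd(30, 20, 1.2), daily_vpd(25, 15, 1.2))
  expect_error(daily_vpd(10, 15, 1), "tmin")
  expect_error(daily_vpd(20, 10, -0.1), "ea")
})

test_that("thermal time is zero below base, linear between, capped above optimum", {
  expect_equal(thermal_time_increment(5, 5, 30), 0)
  expect_equal(thermal_time_increment(2, 5, 30), 0)
  expect_equal(thermal_time_increment(12, 0, 30), 12)
  expect_equal(thermal_time_increment(38, 8, 30), 22)
  expect_error(thermal_time_increment(10, 30, 5), "t_base")
})

test_that("canopy temperature warms under stress and cools under transpiration", {
  expect_equal(canopy_temperature(25, 1, d_heat = 5, d_cool = 2), 23)
  expect_equal(canopy_temperature(25, 0, d_heat = 5, d_cool = 2), 30)
  expect_equal(canopy_temperature(25, 0.3, d_heat = 0, d_cool = 0), 25)
  fw <- seq(0, 1, 0.1)
  expect_true(all(diff(canopy_temperature(25, fw)) < 0))
  expect_error(canopy_temperature(25, 1.2), "f_w")
})

test_that("heat retention follows the exceedance sum and is clamped", {
  expect_equal(heat_stress_retention(c(28, 30, 31), 31, 0.05), 1)
  expect_equal(heat_stress_retention(33, 31, 0.05), 0.90)
  expect_equal(heat_stress_retention(rep(60, 10), 31, 0.05), 0)
  expect_error(heat_stress_retention(30, 31, -0.1), "non-negative")
})

test_that("CO2 factors are 1 at ambient and act by crop class", {
  for (cls in c("C3", "C4")) {
    f <- co2_factors(cls, 360, beta_rue = 0.08, gamma_te = 0.2, lambda_lai = 0.04)
    expect_equal(unlist(f), c(rue_mult = 1, te_mult = 1, lai_mult = 1))
  }
  c4 <- co2_factors("C4", 571, gamma_te = 0.2)
  expect_identical(c4$rue_mult, 1)
  expect_identical(c4$lai_mult, 1)
  expect_gt(c4$te_mult, 1)
  # independent evaluation of 1 + 0.08 ln(571/360)
  c3 <- co2_factors("C3", 571, beta_rue = 0.08, gamma_te = 0.2)
  expect_equal(c3$rue_mult, 1.0369, tolerance = 1e-3)
  expect_error(co2_factors("C3", 300), "360")
})

test_that("transpiration demand is linear in VPD and falls with TE gains", {
  expect_equal(transpiration_demand(20, 0, 5), 0)
  expect_equal(transpiration_demand(20, 2.4, 5), 2 * transpiration_demand(20, 1.2, 5))
  expect_equal(transpiration_demand(20, 1.2, 5, te_mult = 1.1),
               transpiration_demand(20, 1.2, 5) / 1.1)
  expect_error(transpiration_demand(20, 1.2, 0), "te_c")
})

test_that("the soil bucket honours irrigation, emptiness and exact conservation", {
  full <- water_balance_step(80, 0, 6, tawc = 120, irrigation = TRUE)
  expect_identical(full$f_w, 1)
  expect_equal(full$supply, 6)
  empty <- water_balance_step(0, 0, 5, tawc = 120)
  expect_equal(empty$f_w, 0)
  expect_equal(empty$supply, 0)

  # bookkeeping oracle on a random 100-day trajectory
  set.seed(31)
  state <- 60
  sums <- c(precip = 0, irr = 0, supply = 0, drain = 0)
  for (d in 1:100) {
    p <- rgamma(1, 0.6, scale = 8) * rbinom(1, 1, 0.4)
    dem <- runif(1, 0, 7)
    irr_on <- runif(1) < 0.3
    st <- water_balance_step(state, p, dem, tawc = 90, irrigation = irr_on)
    sums <- sums + c(p, st$irrigation, st$supply, st$drainage)
    state <- st$state
  }
  # irrigation is consumed in-step, so it cancels inside the supply term
  residual <- sums["precip"] + sums["irr"] - sums["supply"] - sums["drain"] -
    (state - 60)
  expect_lt(abs(residual), 1e-9)
  expect_error(water_balance_step(50, 0, -1, 120), "demand")
  expect_error(water_balance_step(-5, 0, 1, 120), "state")
})

test_that("crop parameter invariants are enforced", {
  expect_error(crop_parameters("grain_maize", beta_rue = 0.05), "C4")
  expect_error(crop_parameters("winter_wheat", t_base = 30), "cardinal")
  expect_error(crop_parameters("winter_wheat", tt_anth = 2000), "anthesis")
  expect_error(crop_parameters("winter_wheat", rue = -1), "positive")
  expect_error(crop_parameters("winter_wheat", nonsense = 1), "unknown")
})

test_that("a season with no radiation yields nothing", {
  w <- fixture_weather()
  w$rad <- rep(0, nrow(w))
  s <- simulate_season(w, 140, crop_parameters("grain_maize"), "T1")
  expect_equal(s$yield, 0)
  expect_equal(s$biomass, 0)
})

test_that("uniform warming brings maturity strictly earlier", {
  w <- fixture_weather(band = "temperate")
  warm <- apply_delta_change(w, scenario_deltas("w2", dtemp = rep(2, 12)))
  for (preset in c("winter_wheat", "grain_maize")) {
    p <- crop_parameters(preset)
    base <- simulate_season(w, 140, p, "T1")
    shifted <- simulate_season(warm, 140, p, "T1")
    expect_true(base$matured && shifted$matured)
    expect_lt(shifted$maturity_day, base$maturity_day)
  }
})

test_that("stress treatments never out-yield the potential run", {
  w <- fixture_weather(band = "mediterranean", seed = 12)
  p <- crop_parameters("grain_maize")
  y <- vapply(paste0("T", 1:6),
              function(tr) simulate_season(w, 120, p, tr)$yield, numeric(1))
  expect_gte(y["T1"], y["T2"])
  expect_gte(y["T1"], y["T4"])
  expect_gte(y["T4"], y["T6"])
  expect_gte(y["T3"], y["T2"]) # transpirational cooling under irrigation
  expect_lt(y["T4"], y["T1"]) # drought actually bites in this climate
})

test_that("heat-triggered senescence can only reduce growth", {
  w <- fixture_weather(band = "mediterranean", seed = 12)
  # lowered threshold and a pre-anthesis window guarantee the trigger fires
  # while the leaf canopy is still expanding
  base <- crop_parameters("grain_maize", t_crit = 25, heat_window = c(600, 200))
  senes <- crop_parameters("grain_maize", t_crit = 25, heat_window = c(600, 200),
                           senescence_threshold = 1)
  s0 <- simulate_season(w, 120, base, "T5")
  s1 <- simulate_season(w, 120, senes, "T5")
  expect_gt(s0$heat_sum, 1)
  expect_lte(s1$biomass, s0$biomass)
  expect_lt(s1$biomass, s0$biomass) # LAI capping visibly bites
})

test_that("degenerate weather inputs are rejected", {
  w <- fixture_weather()
  p <- crop_parameters("grain_maize")
  start <- which(w$doy == p$sow_doy)[1]
  expect_error(simulate_season(w[start + 0:99, ], 140, p, "T1"), "shorter")
  w_bad <- w
  w_bad$tavg[200] <- NA
  expect_error(simulate_season(w_bad, 140, p, "T1"), "missing")
  expect_error(simulate_season(w, 140, p, "T9"), "unknown treatment")
})
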