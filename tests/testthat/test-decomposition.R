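test_that("loss formulas reproduce their defining arithmetic", {
  expect_equal(drought_loss(10, 7), 30)
  expect_equal(drought_loss(10, 10), 0)
  expect_equal(drought_loss(10, 0), 100)
  expect_error(drought_loss(0, 0), "positive")

  expect_equal(heat_loss_irrigated(8, 6), 25)
  expect_equal(heat_loss_irrigated(8, 8), 0)
  expect_error(heat_loss_irrigated(8, -1), "y_hl")

  expect_equal(heat_loss_rainfed(7, 6, 10), 10)
  expect_equal(heat_loss_rainfed(7, 7, 10), 0)
  expect_error(heat_loss_rainfed(6, 7, 10), "ordering")

  expect_equal(potential_change(9, 10), -10)
  expect_equal(potential_change(11, 10), 10)
  expect_equal(potential_change(10, 10), 0)

  expect_equal(loss_change(31, 20), 11)
  expect_equal(loss_change(20, 31), -11)
  expect_error(loss_change(120, 10), "0, 100")

  expect_equal(co2_effect(25, 30), 5)
  expect_equal(co2_effect(30, 25), -co2_effect(25, 30))
})

test_that("drought plus rainfed heat loss equals the combined loss exactly", {
  set.seed(9)
  y_pot <- runif(500, 4, 14)
  y_wl <- y_pot * runif(500)
  y_wh <- y_wl * runif(500)
  lhs <- drought_loss(y_pot, y_wl) + heat_loss_rainfed(y_wl, y_wh, y_pot)
  rhs <- 100 * (y_pot - y_wh) / y_pot
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  # and the whole thing is scale free
  s <- 3.7
  expect_equal(drought_loss(s * y_pot, s * y_wl), drought_loss(y_pot, y_wl))
})

test_that("the lowest decile picks ceiling(n/10) years, earliest on ties", {
  y <- c(5, 3, 8, 1, 9, 4, 7, 2, 6, 10, 11, 12, 0.5, 13, 14, 15, 16, 17, 18,
         19, 20, 21, 22, 23, 24, 25, 26, 27, 28, 29)
  sel <- lowest_decile_years(y, 1971:2000)
  expect_length(sel, 3)
  expect_setequal(sel, c(1974, 1983, 1978)) # years of the 3 smallest yields
  inc <- lowest_decile_years(1:30, 1:30)
  expect_identical(inc, 1:3)
  ties <- lowest_decile_years(rep(5, 12), 2001:2012)
  expect_identical(ties, 2001:2002)
  expect_error(lowest_decile_years(1:9), "10 years")
})

test_that("decompose propagates a heat-free simulator as exactly zero heat loss", {
  grid <- fixture_grid(3, crops = "grain_maize",
                       lat_band = c("mediterranean", "mediterranean"))
  scen <- scenario_set(rcps = "rcp85", gcms = "hot-dry")
  no_heat <- make_ensemble(crop_parameters("grain_maize", heat_slope = 0),
                           ensemble_spec(2, seed = 4))
  ft <- run_factorial(grid, scen, list(grain_maize = no_heat), n_years = 3,
                      seed = 6)
  agg <- aggregate_for_decomposition(ft, grid, "region")
  dec <- decompose(agg, decile = FALSE)
  d <- tidy(dec)
  expect_true(all(d$heat_loss_rainfed == 0))
  expect_true(all(d$heat_loss_irrigated == 0))
  expect_true(all(d$drought_loss >= 0))
})

test_that("decompose computes changes against the baseline and medians degenerate", {
  fx <- fixture_factorial(n_cells = 2, n_years = 3, n_models = 1,
                          lat_band = c("mediterranean", "mediterranean"))
  agg <- aggregate_for_decomposition(fx$table, fx$grid, "region")
  dec <- decompose(agg, decile = FALSE)
  d <- tidy(dec)
  base_rows <- dplyr::filter(d, scenario == "baseline")
  expect_true(all(is.na(base_rows$potential_change)))
  scen_rows <- dplyr::filter(d, scenario != "baseline")
  expect_true(all(is.finite(scen_rows$potential_change)))
  # single model x single gcm: the ensemble median is the member itself
  s <- dplyr::inner_join(
    dec$summary,
    tidyr::pivot_longer(scen_rows,
                        c("drought_loss", "combined_loss"),
                        names_to = "metric", values_to = "value"),
    by = c("crop", "unit", "scenario", "co2_arm", "subset", "metric")
  )
  expect_equal(s$median, s$value)
  # per-row additivity identity at machine precision
  expect_lt(max(abs(d$combined_loss - d$drought_loss - d$heat_loss_rainfed)),
            1e-9)
})

test_that("air-only members fall back to the air-temperature treatments", {
  fx <- fixture_factorial(n_cells = 2, n_years = 3, n_models = 2,
                          lat_band = c("mediterranean", "mediterranean"))
  agg <- aggregate_for_decomposition(fx$table, fx$grid, "region")
  dec_all <- decompose(agg, decile = FALSE)
  dec_air <- decompose(agg, canopy_models = "m1", decile = FALSE)
  wide <- tidyr::pivot_wider(agg, names_from = treatment, values_from = yield)
  m2 <- dplyr::filter(dec_air$decomposition, model == "m2")
  m2_all <- dplyr::filter(dec_all$decomposition, model == "m2")
  # the fallback uses T2/T5 means, so y_hl/y_wh can only differ there
  expect_equal(m2$y_wl, m2_all$y_wl)
  ref <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(wide, model == "m2"),
                    crop, unit, scenario, gcm, model, co2_arm),
    y_hl = mean(T2), y_wh = mean(T5), .groups = "drop"
  )
  joined <- dplyr::inner_join(dplyr::filter(m2, subset == "all"), ref,
                              by = c("crop", "unit", "scenario", "gcm",
                                     "model", "co2_arm"))
  expect_equal(joined$y_hl.x, joined$y_hl.y)
  expect_equal(joined$y_wh.x, joined$y_wh.y)
})

test_that("tidiers expose the decomposition tables", {
  fx <- fixture_factorial(n_cells = 2, n_years = 3, n_models = 1)
  agg <- aggregate_for_decomposition(fx$table, fx$grid, "region")
  dec <- decompose(agg, decile = FALSE)
  expect_s3_class(tidy(dec), "tbl_df")
  g <- glance(dec)
  expect_equal(g$n_units, 2)
  expect_equal(g$baseline, "baseline")
  expect_s3_class(autoplot(dec), "ggplot")
})
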