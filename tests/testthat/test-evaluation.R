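test_that("moving-window anomalies vanish for constant and linear series", {
  expect_equal(detrend_moving_window(rep(4.2, 12)), rep(0, 12))
  lin <- 2 + 0.3 * (1:15)
  a <- detrend_moving_window(lin)
  expect_lt(max(abs(a[2:14])), 1e-12) # centered windows annihilate the trend
  expect_length(a, 15)
})

test_that("the spike example matches the hand-computed window mean", {
  a <- detrend_moving_window(c(0, 0, 0, 5, 0, 0, 0))
  expect_equal(a[4], 5 - 1) # 5-term window mean is 1
})

test_that("de-trending is equivariant to adding linear functions of year", {
  set.seed(14)
  y <- rnorm(20)
  shifted <- y + 0.7 * (1:20) + 3
  interior <- 2:19
  expect_equal(detrend_moving_window(y)[interior],
               detrend_moving_window(shifted)[interior], tolerance = 1e-12)
})

test_that("the data-frame interface adds anomalies per group", {
  df <- tidyr::crossing(region = c("a", "b"), year = 2001:2010)
  df$yield <- df$year * 0.1 + ifelse(df$region == "a", 5, 8)
  out <- detrend_moving_window(dplyr::group_by(df, region))
  expect_true("anomaly" %in% names(out))
  expect_lt(max(abs(out$anomaly[!out$year %in% c(2001, 2010)])), 1e-12)
  rel <- detrend_moving_window(dplyr::group_by(df, region), relative = TRUE)
  expect_lt(max(abs(rel$anomaly[!rel$year %in% c(2001, 2010)])), 1e-12)
  expect_error(detrend_moving_window(df[c(1, 2, 4, 5), ]), "consecutive")
  expect_error(detrend_moving_window(c(1, 2)), "3 years")
})

test_that("the linear-trend alternative removes straight lines everywhere", {
  lin <- 2 + 0.3 * (1:15)
  expect_lt(max(abs(detrend_moving_window(lin, method = "linear"))), 1e-12)
})

test_that("explained variance is squared correlation with sign flagged", {
  set.seed(3)
  obs <- rnorm(12)
  ev <- explained_variance(obs, obs)
  expect_equal(ev$r_squared, 1)
  expect_false(ev$negative_correlation)
  ev_neg <- explained_variance(obs, -obs)
  expect_equal(ev_neg$r_squared, 1)
  expect_true(ev_neg$negative_correlation)
  orth <- explained_variance(rep(c(1, -1), 4), rep(c(1, 1, -1, -1), 2))
  expect_equal(orth$r_squared, 0)
  expect_true(ev$r_squared >= 0 && ev$r_squared <= 1)
  expect_error(explained_variance(obs, obs[1:5]), "length")
  expect_error(explained_variance(rep(1, 6), rnorm(6)), "zero variance")
})

make_eval_setup <- function(noise_sd = 0, n_cells = 3, n_years = 15,
                            seed = 19, trend_slope = 0.04) {
  grid <- fixture_grid(n_cells, seed = 303,
                       regions = paste0("r", seq_len(n_cells)),
                       lat_band = "mediterranean", crops = "grain_maize")
  scen <- scenario_set(rcps = character(0))
  ens <- fixture_ensembles("grain_maize", n_models = 2)
  ft <- run_factorial(grid, scen, ens, n_years = n_years, seed = 31)
  slice <- dplyr::filter(ft, co2_arm == "ambient")
  truth <- aggregate_yield(
    dplyr::filter(slice, model == "m1", treatment %in% c("T5", "T2")),
    grid, "region", "mix"
  )
  truth <- dplyr::select(dplyr::rename(truth, region = "unit"),
                         region, year, yield)
  obs <- synthesize_observed_yields(truth, trend_slope = trend_slope,
                                    noise_sd = noise_sd, seed = seed)
  list(grid = grid, slice = slice, obs = obs)
}

test_that("noise-free observations built from case-5 truth put case 5 on top", {
  s <- make_eval_setup(noise_sd = 0, trend_slope = 0)
  ev <- evaluate_cases(s$obs, s$slice, s$grid)
  d <- dplyr::filter(tidy(ev), model == "m1")
  c5 <- dplyr::filter(d, case == 5)
  expect_equal(c5$r_squared, rep(1, nrow(c5)), tolerance = 1e-9)
  # case 5 is maximal in every region (drought-free cases may tie with it)
  by_region <- split(d, d$region)
  for (dd in by_region) {
    expect_gte(dd$r_squared[dd$case == 5],
               max(dd$r_squared) - 1e-9)
  }
})

test_that("significance counting honours alpha and reports missing means", {
  s <- make_eval_setup(noise_sd = 0.2)
  all_in <- evaluate_cases(s$obs, s$slice, s$grid, alpha = 1)
  expect_true(all(all_in$summary$n_significant == all_in$summary$n_models))
  none <- evaluate_cases(s$obs, s$slice, s$grid, alpha = 0)
  expect_true(all(none$summary$n_significant == 0))
  expect_true(all(is.na(none$summary$mean_r2_significant)))
  expect_s3_class(autoplot(all_in), "ggplot")
  expect_s3_class(glance(all_in), "tbl_df")
})

test_that("multi-scenario slices and mismatched years are rejected", {
  s <- make_eval_setup(noise_sd = 0)
  fx <- fixture_factorial(n_cells = 2, n_years = 4)
  expect_error(evaluate_cases(s$obs, fx$table, fx$grid), "single-scenario")
  short_obs <- dplyr::filter(s$obs, year > 3)
  expect_error(evaluate_cases(short_obs, s$slice, s$grid), "different years")
})
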