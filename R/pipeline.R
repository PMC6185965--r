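#' Validate a pipeline configuration
#'
#' The configuration is a nested list (typically read from YAML): `seed`
#' (mandatory — no implicit seeding), `years`, `crops`, `grid` (`n_cells`,
#' `regions`, optional `lat_band`, area/depth settings), `ensemble`
#' (`n_models`, jitter sds, `canopy_capable`), `scenarios` (`rcps`, `gcms`),
#' and optional `evaluation` (`trend_slope`, `noise_sd`, `alpha`),
#' `decomposition`, `sensitivity` and `simulation` (`raw_fraction`) blocks.
#'
#' @param config a list or a path to a YAML file.
#' @return the validated config list, invisibly on success; errors name the
#'   offending key.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  need <- function(key, where, what) {
    if (is.null(where[[key]])) abort(paste0("config key missing: ", what, "$", key))
    where[[key]]
  }
  seed <- need("seed", config, "config")
  assert_scalar_number(seed, "config$seed")
  years <- need("years", config, "config")
  if (years < 1) abort("config$years must be >= 1")
  crops <- need("crops", config, "config")
  bad <- setdiff(crops, c("winter_wheat", "grain_maize"))
  if (length(bad)) abort(paste("config$crops: unknown preset(s):",
                               paste(bad, collapse = ", ")))
  grid <- need("grid", config, "config")
  need("n_cells", grid, "config$grid")
  regions <- need("regions", grid, "config$grid")
  if (!is.null(grid$lat_band) && length(grid$lat_band) != length(regions)) {
    abort("config$grid$lat_band must match config$grid$regions in length")
  }
  ens <- need("ensemble", config, "config")
  need("n_models", ens, "config$ensemble")
  scen <- need("scenarios", config, "config")
  need("rcps", scen, "config$scenarios")
  need("gcms", scen, "config$scenarios")
  invisible(config)
}

.write_output <- function(df, path, name, seed) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(sprintf("# cropstress %s v1; seed=%s", name, format(seed)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  path
}

#' Run the full pipeline from a configuration
#'
#' Executes generate (grid + weather) -> simulate (treatment factorial) ->
#' aggregate -> decompose -> evaluate -> uncertainty decomposition, writing
#' five versioned CSV tables (`factorial`, `aggregated`, `decomposition`,
#' `evaluation`, `sensitivity`) plus a `run_log.yaml` with every seed and
#' parameter into `out_dir`. The run is a pure function of the configuration:
#' rerunning with the same config reproduces all outputs bit-identically.
#' Partial outputs are removed if any stage fails.
#'
#' @param config list or YAML path (see [validate_pipeline_config()]).
#' @param out_dir output directory (created if absent).
#' @param dry_run validate the configuration and return it without simulating.
#' @param plots also write summary figures (PNG) for the decomposition and
#'   sensitivity stages.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`grid`, `factorial`,
#'   `aggregated`, `decomposition`, `evaluation`, `sensitivity`, `observed`)
#'   and the written `paths`.
#' @export
run_pipeline <- function(config, out_dir = "cropstress_out", dry_run = FALSE,
                         plots = FALSE, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  if (dry_run) return(invisible(config))
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  result <- tryCatch({
    say("generating grid")
    grid_cfg <- config$grid
    plan <- region_plan(
      regions = grid_cfg$regions,
      lat_band = grid_cfg$lat_band %||% "temperate",
      crops = config$crops,
      mean_rainfed = grid_cfg$mean_rainfed %||% 8000,
      mean_irrigated = grid_cfg$mean_irrigated %||% 1500,
      depth_mean = grid_cfg$depth_mean %||% 95,
      depth_sd = grid_cfg$depth_sd %||% 30
    )
    grid <- generate_grid(grid_cfg$n_cells, mix_seed(seed, "grid"), plan)

    scen <- scenario_set(config$scenarios$rcps, config$scenarios$gcms)
    ens_cfg <- config$ensemble
    ensembles <- lapply(setNames(config$crops, config$crops), function(crop) {
      make_ensemble(
        crop_parameters(crop),
        ensemble_spec(
          n_models = ens_cfg$n_models,
          seed = mix_seed(seed, "ensemble"),
          sd_rue = ens_cfg$sd_rue %||% 0.06,
          sd_te = ens_cfg$sd_te %||% 0.06,
          sd_tt = ens_cfg$sd_tt %||% 0.04,
          sd_heat_slope = ens_cfg$sd_heat_slope %||% 0.15,
          sd_co2 = ens_cfg$sd_co2 %||% 0.10,
          canopy_capable = unlist(ens_cfg$canopy_capable %||% TRUE)
        )
      )
    })
    canopy_tbl <- attr(ensembles[[1]], "canopy")
    canopy_models <- canopy_tbl$model[canopy_tbl$canopy_capable]

    say("running the treatment factorial")
    factorial <- run_factorial(
      grid, scen, ensembles, n_years = config$years, seed = seed,
      raw_fraction = config$simulation$raw_fraction %||% 0.5
    )

    say("aggregating")
    agg <- dplyr::bind_rows(
      aggregate_for_decomposition(factorial, grid, level = "region"),
      aggregate_for_decomposition(factorial, grid, level = "all")
    )

    say("decomposing losses")
    dec <- decompose(agg, baseline = "baseline", canopy_models = canopy_models,
                     decile = config$years >= 10)

    say("evaluating against synthetic observations")
    ev_cfg <- config$evaluation %||% list()
    base_slice <- dplyr::filter(factorial, .data$scenario == "baseline",
                                .data$co2_arm == "ambient")
    truth <- aggregate_yield(
      dplyr::filter(base_slice, .data$model == "m1",
                    .data$treatment %in% c("T4", "T1")),
      grid, level = "region", regime = "mix"
    )
    truth <- dplyr::select(dplyr::rename(truth, region = "unit"),
                           dplyr::all_of(c("crop", "region", "year", "yield")))
    observed <- purrr::map_dfr(split(truth, truth$crop), function(tr) {
      dplyr::mutate(
        synthesize_observed_yields(
          tr, trend_slope = ev_cfg$trend_slope %||% 0.05,
          noise_sd = ev_cfg$noise_sd %||% 0.25,
          seed = mix_seed(seed, "obs", tr$crop[1])
        ),
        crop = tr$crop[1]
      )
    })
    evaluation <- evaluate_cases(observed, base_slice, grid,
                                 alpha = ev_cfg$alpha %||% 0.05)

    say("decomposing uncertainty")
    eu_mix <- aggregate_yield(
      dplyr::filter(factorial, .data$scenario != "baseline",
                    .data$treatment %in% c("T6", "T3")),
      grid, level = "all", regime = "mix"
    )
    eu_mean <- dplyr::summarise(
      dplyr::group_by(eu_mix, .data$crop, .data$scenario, .data$gcm,
                      .data$model, .data$co2_arm),
      yield = mean(.data$yield), .groups = "drop"
    )
    sens <- decompose_uncertainty(
      eu_mean,
      collapse_replicates = !isFALSE(config$sensitivity$collapse_replicates)
    )

    say("writing outputs")
    paths <- c(
      factorial = .write_output(factorial, file.path(out_dir, "factorial.csv"),
                                "factorial", seed),
      aggregated = .write_output(agg, file.path(out_dir, "aggregated.csv"),
                                 "aggregated", seed),
      decomposition = .write_output(dec$decomposition,
                                    file.path(out_dir, "decomposition.csv"),
                                    "decomposition", seed),
      evaluation = .write_output(evaluation$summary,
                                 file.path(out_dir, "evaluation.csv"),
                                 "evaluation", seed),
      sensitivity = .write_output(tibble::as_tibble(sens),
                                  file.path(out_dir, "sensitivity.csv"),
                                  "sensitivity", seed)
    )
    written <- paths
    log_path <- file.path(out_dir, "run_log.yaml")
    yaml::write_yaml(
      list(config = config,
           derived_seeds = list(grid = mix_seed(seed, "grid"),
                                ensemble = mix_seed(seed, "ensemble")),
           n_factorial_rows = nrow(factorial),
           canopy_models = canopy_models),
      log_path
    )
    written <- c(written, log = log_path)

    if (plots) {
      for (pl in list(list(file = "decomposition.png", obj = autoplot(dec)),
                      list(file = "sensitivity.png", obj = autoplot(sens)))) {
        p <- file.path(out_dir, pl$file)
        tryCatch({
          ggplot2::ggsave(p, pl$obj, width = 9, height = 6, dpi = 120)
          written <- c(written, p)
        }, error = function(e) say("plot skipped: ", conditionMessage(e)))
      }
    }

    list(grid = grid, factorial = factorial, aggregated = agg,
         decomposition = dec, evaluation = evaluation, sensitivity = sens,
         observed = observed, paths = written)
  }, error = function(e) {
    file.remove(written[file.exists(written)])
    abort(paste("pipeline failed:", conditionMessage(e)), parent = e)
  })
  invisible(result)
}

#' Path to the shipped stylized-Europe example configuration
#'
#' Six regions across three latitude bands, 60 grid cells, 30 harvest years,
#' baseline plus two forcing-pathway analogues with two climate-model
#' analogues each, four pseudo-models, both crop presets.
#'
#' @return path to the YAML file installed with the package.
#' @export
stylized_europe_config <- function() {
  system.file("examples", "stylized_europe.yaml", package = "cropstress",
              mustWork = TRUE)
}
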