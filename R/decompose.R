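#' Loss and change metrics of the yield decomposition
#'
#' All losses are expressed in percent of the relevant potential yield, so they
#' are invariant to uniform rescaling of yields:
#' * `drought_loss(y_pot, y_wl)`: `100 * (y_pot - y_wl) / y_pot`.
#' * `heat_loss_irrigated(y_pot, y_hl)`: `100 * (y_pot - y_hl) / y_pot`, with
#'   the heat-limited yield from the canopy treatment for canopy-capable
#'   members and the air treatment otherwise.
#' * `heat_loss_rainfed(y_wl, y_wh, y_pot)`: `100 * (y_wl - y_wh) / y_pot`, the
#'   extra loss of combined heat-and-drought beyond drought alone; together
#'   with the drought loss it sums exactly to the combined loss
#'   `100 * (y_pot - y_wh) / y_pot`.
#' * `potential_change(y_pot_scen, y_pot_base)`: signed percent change in
#'   potential yields vs the baseline potential (the mean-temperature effect).
#' * `loss_change(loss_scen, loss_base)`: percentage-point difference of losses
#'   each taken relative to its own period's potential.
#' * `co2_effect(metric_with, metric_without)`: `without - with`; positive
#'   values mean CO2 fertilization alleviates the loss.
#'
#' @param y_pot,y_wl,y_hl,y_wh potential, water-limited, heat-limited and
#'   combined-limited yields (t ha-1); orderings `0 <= y_wh <= y_wl <= y_pot`
#'   and `0 <= y_hl <= y_pot` are enforced (violations indicate a broken
#'   simulator monotonicity).
#' @param y_pot_scen,y_pot_base scenario and baseline potential yields.
#' @param loss_scen,loss_base losses in percent, each within `[0, 100]`.
#' @param metric_with,metric_without a loss metric with and without CO2
#'   fertilization.
#' @return numeric vectors (percent, or percentage points for the changes).
#' @name loss_metrics
NULL

.tol <- 1e-9

#' @rdname loss_metrics
#' @export
drought_loss <- function(y_pot, y_wl) {
  if (any(y_pot <= 0)) abort("`y_pot` must be positive")
  if (any(y_wl < -.tol) || any(y_wl > y_pot + .tol)) {
    abort("need 0 <= y_wl <= y_pot")
  }
  100 * (y_pot - y_wl) / y_pot
}

#' @rdname loss_metrics
#' @export
heat_loss_irrigated <- function(y_pot, y_hl) {
  if (any(y_pot <= 0)) abort("`y_pot` must be positive")
  if (any(y_hl < -.tol) || any(y_hl > y_pot + .tol)) {
    abort("need 0 <= y_hl <= y_pot")
  }
  100 * (y_pot - y_hl) / y_pot
}

#' @rdname loss_metrics
#' @export
heat_loss_rainfed <- function(y_wl, y_wh, y_pot) {
  if (any(y_pot <= 0)) abort("`y_pot` must be positive")
  if (any(y_wh < -.tol) || any(y_wh > y_wl + .tol) || any(y_wl > y_pot + .tol)) {
    abort("yield ordering y_wh <= y_wl <= y_pot violated (simulator monotonicity bug?)")
  }
  100 * (y_wl - y_wh) / y_pot
}

#' @rdname loss_metrics
#' @export
potential_change <- function(y_pot_scen, y_pot_base) {
  if (any(y_pot_base <= 0)) abort("`y_pot_base` must be positive")
  100 * (y_pot_scen - y_pot_base) / y_pot_base
}

#' @rdname loss_metrics
#' @export
loss_change <- function(loss_scen, loss_base) {
  if (any(c(loss_scen, loss_base) < -.tol) ||
      any(c(loss_scen, loss_base) > 100 + .tol)) {
    abort("losses must lie in [0, 100] percent")
  }
  loss_scen - loss_base
}

#' @rdname loss_metrics
#' @export
co2_effect <- function(metric_with, metric_without) {
  metric_without - metric_with
}

#' Years in the lowest yield decile
#'
#' The `ceiling(n/10)` years with the smallest yields; ties are broken in favor
#' of earlier years.
#'
#' @param yields numeric yields, one per year.
#' @param years the year labels (defaults to `seq_along(yields)`).
#' @return the selected year labels.
#' @export
lowest_decile_years <- function(yields, years = seq_along(yields)) {
  n <- length(yields)
  if (n < 10) abort("need at least 10 years for a decile analysis")
  if (length(years) != n) abort("`years` must match `yields` in length")
  k <- ceiling(n / 10)
  years[order(yields, years)[seq_len(k)]]
}

#' Decompose aggregated yields into mean-temperature, drought and heat drivers
#'
#' For every (crop, unit, scenario, GCM-analogue, model, CO2 arm), losses are
#' computed from multi-year mean yields of the rainfed-land aggregates: drought
#' loss from T1 vs T4, irrigated heat loss from T1 vs T3 (T2 for members
#' without a canopy-temperature routine), rainfed heat loss from T4 vs T6 (T5),
#' and the combined loss from T1 vs T6 (T5). Scenario rows additionally carry
#' the potential change vs the baseline and percentage-point loss changes. The
#' whole set is computed for all years and, when at least 10 years are present,
#' for the years in the lowest yield decile of the fully limited treatment of
#' the same CO2 arm. Ensemble medians and 10th/90th percentiles across model x
#' GCM combinations are returned alongside the per-member detail.
#'
#' @param agg aggregated yields as returned by [aggregate_for_decomposition()]:
#'   columns `crop`, `unit`, `scenario`, `gcm`, `model`, `treatment`,
#'   `co2_arm`, `year`, `yield`.
#' @param baseline scenario id of the baseline period.
#' @param canopy_models character vector of canopy-capable model ids; defaults
#'   to all models in `agg`.
#' @param decile compute the lowest-decile subset (requires >= 10 years).
#' @return a `loss_decomposition` object: list with `decomposition` (per-member
#'   detail, `subset` in `all`/`lowest_decile`) and `summary` (median/p10/p90
#'   across model x GCM per metric).
#' @export
decompose <- function(agg, baseline = "baseline", canopy_models = NULL,
                      decile = TRUE) {
  assert_cols(agg, c("crop", "unit", "scenario", "gcm", "model", "treatment",
                     "co2_arm", "year", "yield"), "agg")
  if (!baseline %in% agg$scenario) abort("baseline scenario not present in `agg`")
  canopy_models <- canopy_models %||% unique(agg$model)

  wide <- tidyr::pivot_wider(agg, names_from = "treatment",
                             values_from = "yield")
  need <- c("T1", "T4", "T2", "T5")
  missing <- setdiff(need, names(wide))
  if (length(missing)) {
    abort(paste("missing treatment(s) in aggregated table:",
                paste(missing, collapse = ", ")))
  }
  if (!all(c("T3", "T6") %in% names(wide))) {
    wide$T3 <- NA_real_
    wide$T6 <- NA_real_
  }
  capable <- wide$model %in% canopy_models & !is.na(wide$T3) & !is.na(wide$T6)
  wide$y_hl <- ifelse(capable, wide$T3, wide$T2)
  wide$y_wh <- ifelse(capable, wide$T6, wide$T5)

  n_years <- length(unique(wide$year))
  do_decile <- decile && n_years >= 10

  one_group <- function(df) {
    rows <- list(all = df)
    if (do_decile) {
      yrs <- lowest_decile_years(df$y_wh, df$year)
      rows$lowest_decile <- df[df$year %in% yrs, , drop = FALSE]
    }
    purrr::imap_dfr(rows, function(d, subset_name) {
      tibble::tibble(
        subset = subset_name,
        y_pot = mean(d$T1), y_wl = mean(d$T4),
        y_hl = mean(d$y_hl), y_wh = mean(d$y_wh)
      )
    })
  }
  key_cols <- c("crop", "unit", "scenario", "gcm", "model", "co2_arm")
  detail <- dplyr::group_modify(
    dplyr::group_by(wide, dplyr::across(dplyr::all_of(key_cols))),
    ~ one_group(.x)
  )
  detail <- dplyr::ungroup(detail)
  detail$drought_loss <- drought_loss(detail$y_pot, detail$y_wl)
  detail$heat_loss_irrigated <- heat_loss_irrigated(detail$y_pot, detail$y_hl)
  detail$heat_loss_rainfed <- heat_loss_rainfed(detail$y_wl, detail$y_wh,
                                                detail$y_pot)
  detail$combined_loss <- 100 * (detail$y_pot - detail$y_wh) / detail$y_pot

  base <- dplyr::filter(detail, .data$scenario == baseline)
  base <- dplyr::select(base, dplyr::all_of(c("crop", "unit", "model", "co2_arm",
                                              "subset")),
                        base_pot = "y_pot", base_drought = "drought_loss",
                        base_heat_rf = "heat_loss_rainfed",
                        base_heat_irr = "heat_loss_irrigated",
                        base_combined = "combined_loss")
  detail <- dplyr::left_join(detail, base,
                             by = c("crop", "unit", "model", "co2_arm", "subset"))
  is_scen <- detail$scenario != baseline
  na_if_base <- function(x) ifelse(is_scen, x, NA_real_)
  detail$potential_change <- na_if_base(
    potential_change(detail$y_pot, detail$base_pot))
  detail$drought_loss_change <- na_if_base(
    loss_change(detail$drought_loss, detail$base_drought))
  detail$heat_loss_rainfed_change <- na_if_base(
    loss_change(detail$heat_loss_rainfed, detail$base_heat_rf))
  detail$heat_loss_irrigated_change <- na_if_base(
    loss_change(detail$heat_loss_irrigated, detail$base_heat_irr))
  detail$combined_loss_change <- na_if_base(
    loss_change(detail$combined_loss, detail$base_combined))
  detail <- dplyr::select(detail, -dplyr::starts_with("base_"))

  metrics <- c("potential_change", "drought_loss", "heat_loss_irrigated",
               "heat_loss_rainfed", "combined_loss", "drought_loss_change",
               "heat_loss_rainfed_change", "heat_loss_irrigated_change",
               "combined_loss_change")
  long <- tidyr::pivot_longer(
    detail[c("crop", "unit", "scenario", "gcm", "model", "co2_arm", "subset",
             metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$crop, .data$unit, .data$scenario,
                    .data$co2_arm, .data$subset, .data$metric),
    median = median(.data$value),
    p10 = unname(quantile(.data$value, 0.10, type = 7)),
    p90 = unname(quantile(.data$value, 0.90, type = 7)),
    n = dplyr::n(), .groups = "drop"
  )

  structure(list(decomposition = detail, summary = summary,
                 baseline = baseline, canopy_models = canopy_models),
            class = "loss_decomposition")
}

#' @export
print.loss_decomposition <- function(x, ...) {
  cat("<loss_decomposition>\n")
  cat("  baseline:", x$baseline, "\n")
  cat("  detail rows:", nrow(x$decomposition),
      " summary rows:", nrow(x$summary), "\n")
  invisible(x)
}

#' Aggregate a factorial table for the loss decomposition
#'
#' All six treatments weighted by rainfed production areas (the decomposition
#' is defined for rainfed systems, with potential yields taken on rainfed
#' land).
#'
#' @param table a factorial table from [run_factorial()].
#' @param areas a `crop_grid`.
#' @param level `"region"` or `"all"`.
#' @return tibble ready for [decompose()].
#' @export
aggregate_for_decomposition <- function(table, areas, level = c("region", "all")) {
  aggregate_yield(table, areas, level = level, regime = "rainfed")
}
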