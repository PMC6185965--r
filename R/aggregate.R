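# grouping keys used when aggregating cell-level yields; only those present in
# the input are used, so slices work as well as full tables
.agg_keys <- c("crop", "scenario", "gcm", "model", "treatment", "co2_arm", "year")

.mix_pairs <- c(T4 = "T1", T5 = "T2", T6 = "T3")

#' Aggregate cell yields to region or EU level by production-area weighting
#'
#' Production is yield times area per cell; the aggregate yield of a unit is its
#' total production divided by its total area — i.e. an area-weighted mean.
#' `regime` selects the weights: rainfed area, irrigated area, their sum
#' (`"total"`), or `"mix"`, which weights the water-limited yield by the
#' rainfed area and the yield of its fully irrigated counterpart treatment
#' (T4-T1, T5-T2, T6-T3) by the irrigated area, approximating the observed mix
#' of rainfed and irrigated production.
#'
#' @param table a factorial table (or slice) with cell-level yields. For
#'   `regime = "mix"` it must contain the water-limited treatments and their
#'   irrigated counterparts.
#' @param areas a `crop_grid` (or tibble) with `cell_id`, `crop`, `region`,
#'   `area_rainfed`, `area_irrigated`.
#' @param level `"region"` or `"all"` (EU aggregate, unit `"EU"`).
#' @param regime `"rainfed"`, `"irrigated"`, `"total"` or `"mix"`.
#' @return a tibble with the grouping keys present in `table`, a `unit` column
#'   and the aggregated `yield` (t ha-1). For `regime = "mix"` the `treatment`
#'   column carries the water-limited member of each pair.
#' @export
aggregate_yield <- function(table, areas,
                            level = c("region", "all"),
                            regime = c("rainfed", "irrigated", "total", "mix")) {
  level <- match.arg(level)
  regime <- match.arg(regime)
  assert_cols(table, c("cell_id", "crop", "yield"), "table")
  assert_cols(areas, c("cell_id", "crop", "region", "area_rainfed",
                       "area_irrigated"), "areas")
  # the areas table is the authority on the cell -> region mapping
  table <- dplyr::select(table, -dplyr::any_of("region"))
  area_tbl <- dplyr::distinct(
    tibble::as_tibble(areas)[c("cell_id", "crop", "region",
                               "area_rainfed", "area_irrigated")]
  )

  if (regime == "mix") {
    assert_cols(table, "treatment", "table")
    rf <- dplyr::filter(table, .data$treatment %in% names(.mix_pairs))
    if (!nrow(rf)) abort("mix aggregation needs water-limited treatments (T4-T6)")
    irr_map <- .mix_pairs[rf$treatment]
    irr <- dplyr::filter(table, .data$treatment %in% unname(.mix_pairs))
    join_keys <- intersect(setdiff(.agg_keys, "treatment"), names(table))
    irr <- dplyr::select(
      dplyr::mutate(irr, irr_of = .data$treatment),
      dplyr::all_of(c(join_keys, "cell_id", "irr_of")), yield_irr = "yield"
    )
    rf <- dplyr::mutate(rf, irr_of = unname(.mix_pairs[.data$treatment]))
    paired <- dplyr::left_join(rf, irr,
                               by = c(join_keys, "cell_id", "irr_of"))
    if (anyNA(paired$yield_irr)) {
      abort("irrigated counterpart treatment missing for mix aggregation")
    }
    data <- dplyr::inner_join(paired, area_tbl, by = c("cell_id", "crop"))
    if (nrow(data) != nrow(paired)) abort("cells missing from `areas`")
    keys <- intersect(.agg_keys, names(table))
    data$unit <- if (level == "region") data$region else "EU"
    grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(c(keys, "unit"))))
    out <- dplyr::summarise(
      grouped,
      production = sum(.data$yield * .data$area_rainfed +
                         .data$yield_irr * .data$area_irrigated),
      area = sum(.data$area_rainfed + .data$area_irrigated),
      .groups = "drop"
    )
  } else {
    data <- dplyr::inner_join(table, area_tbl, by = c("cell_id", "crop"))
    if (nrow(data) != nrow(table)) abort("cells missing from `areas`")
    data$weight <- switch(regime,
      rainfed = data$area_rainfed,
      irrigated = data$area_irrigated,
      total = data$area_rainfed + data$area_irrigated
    )
    keys <- intersect(.agg_keys, names(table))
    data$unit <- if (level == "region") data$region else "EU"
    grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(c(keys, "unit"))))
    out <- dplyr::summarise(grouped,
                            production = sum(.data$yield * .data$weight),
                            area = sum(.data$weight), .groups = "drop")
  }
  if (any(out$area <= 0)) {
    abort("zero total production area in at least one aggregation unit")
  }
  out$yield <- out$production / out$area
  dplyr::select(out, -"production", -"area")
}

#' Potential yield aggregated over rainfed land
#'
#' The potential-treatment slice (T1-T3) weighted by rainfed production areas
#' only, as used throughout the loss decomposition.
#'
#' @inheritParams aggregate_yield
#' @export
potential_on_rainfed_land <- function(table, areas, level = c("region", "all")) {
  assert_cols(table, "treatment", "table")
  slice <- dplyr::filter(table, .data$treatment %in% c("T1", "T2", "T3"))
  if (!nrow(slice)) abort("no potential treatments (T1-T3) in `table`")
  aggregate_yield(slice, areas, level = level, regime = "rainfed")
}

#' Drought environment index
#'
#' The ratio of aggregated water-limited (T4) to potential (T1) yield on
#' rainfed land per unit: 1 where drought never binds, below 1 where it does.
#' Both numerator and denominator use rainfed-area weights so the index is
#' exactly 1 in the absence of drought regardless of the spatial distribution
#' of areas.
#'
#' @inheritParams aggregate_yield
#' @return a tibble with the grouping keys and `environment_index`.
#' @export
environment_index <- function(table, areas, level = c("region", "all")) {
  assert_cols(table, "treatment", "table")
  num <- aggregate_yield(dplyr::filter(table, .data$treatment == "T4"),
                         areas, level = level, regime = "rainfed")
  den <- aggregate_yield(dplyr::filter(table, .data$treatment == "T1"),
                         areas, level = level, regime = "rainfed")
  if (any(den$yield <= 0)) abort("zero potential yield in at least one unit")
  keys <- setdiff(names(num), c("yield", "treatment"))
  out <- dplyr::inner_join(
    dplyr::rename(dplyr::select(num, -"treatment"), y_wl = "yield"),
    dplyr::rename(dplyr::select(den, -"treatment"), y_pot = "yield"),
    by = keys
  )
  out$environment_index <- out$y_wl / out$y_pot
  dplyr::select(out, -"y_wl", -"y_pot")
}
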