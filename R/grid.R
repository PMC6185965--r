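#' Describe how grid cells are allocated to regions
#'
#' @param regions character vector of region ids (at least one).
#' @param lat_band latitude-band label per region (drives the climate profile;
#'   see [lat_band_profile()]); recycled if length one.
#' @param crops crop names carried on every cell.
#' @param mean_rainfed,mean_irrigated mean crop areas per cell (ha) for the
#'   gamma-distributed area draws.
#' @param depth_mean,depth_sd soil-depth distribution (cm) cells are drawn from;
#'   draws below the 40 cm exclusion rule are rejected and redrawn.
#' @param strict if `TRUE`, fail when a cell cannot be drawn with depth >= 40 cm
#'   after `max_redraws`; if `FALSE`, drop such cells (logged via attribute and
#'   message).
#' @param max_redraws redraw budget per cell for the depth exclusion rule.
#' @return a `region_plan` list.
#' @export
region_plan <- function(regions, lat_band = "temperate",
                        crops = c("winter_wheat", "grain_maize"),
                        mean_rainfed = 8000, mean_irrigated = 1500,
                        depth_mean = 95, depth_sd = 30,
                        strict = FALSE, max_redraws = 200) {
  if (length(regions) < 1) abort("`region_plan` needs at least one region")
  if (anyDuplicated(regions)) abort("region ids must be unique")
  lat_band <- rep_len(lat_band, length(regions))
  structure(
    list(regions = as.character(regions), lat_band = lat_band, crops = crops,
         mean_rainfed = mean_rainfed, mean_irrigated = mean_irrigated,
         depth_mean = depth_mean, depth_sd = depth_sd,
         strict = strict, max_redraws = as.integer(max_redraws)),
    class = "region_plan"
  )
}

#' Generate a synthetic simulation grid
#'
#' Emulates the gridded soil and crop-area inputs: each cell gets a soil profile
#' (depth, TAWC, wilting point, derived field capacity, saturation, texture) and
#' rainfed/irrigated areas per crop. Cells are assigned to regions round-robin so
#' every cell belongs to exactly one region. Soils drawn shallower than 40 cm are
#' rejected and redrawn; the rejection count is recorded in the `"rejections"`
#' attribute.
#'
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; the grid is a pure function of `(n_cells, seed, plan)`.
#' @param plan a [region_plan()].
#' @return a `crop_grid` tibble with one row per cell x crop: `cell_id`,
#'   `region`, `lat_band`, soil columns, `crop`, `area_rainfed`,
#'   `area_irrigated` (ha).
#' @export
generate_grid <- function(n_cells, seed, plan) {
  stopifnot(inherits(plan, "region_plan"))
  if (!is.numeric(n_cells) || n_cells < 1 || n_cells != round(n_cells)) {
    abort("`n_cells` must be a positive whole number")
  }
  assert_scalar_number(seed, "seed")
  n_cells <- as.integer(n_cells)

  with_seed(seed, {
    reg_idx <- rep_len(seq_along(plan$regions), n_cells)
    depth <- numeric(n_cells)
    rejections <- 0L
    keep <- rep(TRUE, n_cells)
    for (i in seq_len(n_cells)) {
      d <- rnorm(1, plan$depth_mean, plan$depth_sd)
      tries <- 0L
      while (d < 40 && tries < plan$max_redraws) {
        rejections <- rejections + 1L
        d <- rnorm(1, plan$depth_mean, plan$depth_sd)
        tries <- tries + 1L
      }
      if (d < 40) {
        rejections <- rejections + 1L
        if (plan$strict) {
          abort("could not draw a soil with depth >= 40 cm within the redraw budget")
        }
        keep[i] <- FALSE
      }
      depth[i] <- d
    }
    wp <- runif(n_cells, 0.08, 0.18)
    awc_per_cm <- runif(n_cells, 1.2, 2.0) # mm available water per cm of depth
    tawc <- depth * awc_per_cm
    texture <- sample(c("loam", "clay_loam", "sandy_loam"), n_cells, replace = TRUE)

    cells <- tibble::tibble(
      cell_id = sprintf("C%03d", seq_len(n_cells)),
      region = plan$regions[reg_idx],
      lat_band = plan$lat_band[reg_idx],
      depth = depth, tawc = tawc, wp = wp, texture = texture
    )[keep, , drop = FALSE]
    if (!all(keep)) {
      message(sprintf("dropped %d cell(s) that violated the 40 cm depth rule",
                      sum(!keep)))
    }
    if (nrow(cells)) {
      cells$fc <- derive_field_capacity(cells$wp, cells$tawc, cells$depth)
      cells$saturation <- cells$fc + runif(nrow(cells), 0.08, 0.15)
    } else {
      cells$fc <- numeric(0)
      cells$saturation <- numeric(0)
    }

    out <- tidyr::crossing(cells, crop = plan$crops)
    nr <- nrow(out)
    out$area_rainfed <- rgamma(nr, shape = 4, scale = plan$mean_rainfed / 4)
    out$area_irrigated <- rgamma(nr, shape = 2, scale = plan$mean_irrigated / 2)
    out <- dplyr::arrange(out, .data$cell_id, .data$crop)
    attr(out, "rejections") <- rejections
    attr(out, "seed") <- seed
    class(out) <- c("crop_grid", class(out))
    out
  })
}

#' Synthesize an "observed" regional yield series from a simulated truth
#'
#' Adds a technology-like linear trend, an intercept, and Gaussian noise to a
#' region-level simulated yield series, providing the observation analogue the
#' evaluation stage de-trends and correlates. The generating truth metadata is
#' kept in attributes for test assertions.
#'
#' @param truth tibble with columns `region`, `year`, `yield` (>= 3 consecutive
#'   years per region).
#' @param trend_slope linear trend (t ha-1 yr-1).
#' @param noise_sd Gaussian noise sd (t ha-1), >= 0.
#' @param seed integer seed.
#' @param intercept additive offset (t ha-1).
#' @return tibble `(region, year, yield)` with yields floored at a small
#'   positive value; attributes `trend_slope`, `noise_sd`, `intercept`, `seed`.
#' @export
synthesize_observed_yields <- function(truth, trend_slope = 0, noise_sd = 0,
                                       seed = 1, intercept = 0) {
  assert_cols(truth, c("region", "year", "yield"), "truth")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative")
  assert_scalar_number(seed, "seed")
  counts <- dplyr::count(truth, .data$region)
  if (any(counts$n < 3)) abort("each region needs at least 3 years of truth")
  gaps <- dplyr::summarise(
    dplyr::group_by(truth, .data$region),
    ok = all(diff(sort(.data$year)) == 1), .groups = "drop"
  )
  if (!all(gaps$ok)) abort("truth years must be consecutive within each region")

  with_seed(seed, {
    out <- dplyr::mutate(
      dplyr::group_by(truth, .data$region),
      yield = .data$yield + trend_slope * (.data$year - min(.data$year)) +
        intercept + rnorm(dplyr::n(), 0, noise_sd)
    )
    out <- dplyr::ungroup(out)
    out$yield <- pmax(out$yield, 0.01)
    attr(out, "trend_slope") <- trend_slope
    attr(out, "noise_sd") <- noise_sd
    attr(out, "intercept") <- intercept
    attr(out, "seed") <- seed
    out
  })
}
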