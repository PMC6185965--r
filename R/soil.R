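#' Derive volumetric field capacity from wilting point, TAWC and depth
#'
#' `FC = WP + TAWC / (10 * depth)`: the factor 10 converts the rooting depth in
#' cm into mm of water per unit volumetric fraction. Profiles shallower than
#' 40 cm are excluded from the study design and rejected here.
#'
#' @param wp volumetric wilting point, in `(0, 1)`.
#' @param tawc total available water content over the profile (mm), >= 0.
#' @param depth rooting depth (cm), >= 40.
#' @param saturation optional volumetric saturation; if supplied, an FC at or
#'   above it is an error.
#' @return volumetric field capacity (vectorized).
#' @export
derive_field_capacity <- function(wp, tawc, depth, saturation = NULL) {
  if (any(depth < 40)) abort("soil depth < 40 cm is excluded from the design")
  if (any(tawc < 0)) abort("`tawc` must be non-negative")
  if (any(wp <= 0 | wp >= 1)) abort("`wp` must be a volumetric fraction in (0, 1)")
  fc <- wp + tawc / (10 * depth)
  if (!is.null(saturation) && any(fc >= saturation)) {
    abort("derived field capacity reaches saturation; inconsistent profile")
  }
  fc
}

#' Initial profile water at sowing
#'
#' The profile starts the season at 30% depletion of the readily available
#' water: `TAWC - 0.3 * raw_fraction * TAWC`. The readily available fraction
#' defaults to 0.5 of TAWC (the standard FAO-56 depletion fraction).
#'
#' @param tawc total available water content (mm), or a data frame with a
#'   `tawc` column.
#' @param raw_fraction fraction of TAWC that is readily available, in `(0, 1]`.
#' @return initial soil water (mm), in `[0, TAWC]`.
#' @export
initial_soil_water <- function(tawc, raw_fraction = 0.5) {
  if (is.data.frame(tawc)) tawc <- tawc$tawc
  assert_scalar_number(raw_fraction, "raw_fraction", lo = 1e-12, hi = 1)
  if (any(tawc < 0)) abort("`tawc` must be non-negative")
  tawc - 0.3 * raw_fraction * tawc
}

#' Construct a soil profile record
#'
#' @param depth rooting depth (cm), >= 40.
#' @param tawc total available water content (mm).
#' @param wp volumetric wilting point.
#' @param saturation volumetric saturation.
#' @param texture_top,texture_sub texture class labels.
#' @return a one-row tibble with `fc` derived via [derive_field_capacity()].
#' @export
soil_profile <- function(depth, tawc, wp, saturation = NULL,
                         texture_top = "loam", texture_sub = texture_top) {
  fc <- derive_field_capacity(wp, tawc, depth, saturation)
  saturation <- saturation %||% (fc + 0.1)
  if (any(wp >= fc) || any(fc > saturation) || any(saturation >= 1)) {
    abort("soil profile must satisfy 0 < WP < FC <= saturation < 1")
  }
  tibble::tibble(depth = depth, tawc = tawc, wp = wp, fc = fc,
                 saturation = saturation,
                 texture_top = texture_top, texture_sub = texture_sub)
}
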