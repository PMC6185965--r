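.detrend_window_means <- function(y) {
  n <- length(y)
  vapply(seq_len(n), function(t) {
    idx <- if (t == 1) {
      1:2
    } else if (t == n) {
      (n - 1):n
    } else if (t == 2 || t == n - 1) {
      (t - 1):(t + 1)
    } else {
      (t - 2):(t + 2)
    }
    mean(y[idx])
  }, numeric(1))
}

#' De-trend a yield series by a centered moving mean
#'
#' Annual anomalies relative to a 5-year moving mean (t-2 .. t+2) with 3-year
#' windows (t-1 .. t+1) at the second and penultimate positions; the outermost
#' years, where a centered 3-year window does not exist, use the two available
#' years. Centered windows annihilate linear trends, so interior anomalies of
#' an exactly linear series are zero. A linear-trend alternative
#' (`method = "linear"`, residuals of a straight-line fit) is also provided.
#'
#' @param data a data frame with one row per year (grouped data frames are
#'   de-trended per group), or a bare numeric vector of yields.
#' @param value,year column names of the yield and year (defaults `yield`,
#'   `year`).
#' @param method `"window"` (moving mean) or `"linear"`.
#' @param relative if `TRUE`, anomalies are `(y - m)/m` instead of `y - m`.
#' @return the input with an `anomaly` column appended (or a numeric vector of
#'   anomalies when `data` is a vector). Years must be consecutive; at least
#'   3 years are required.
#' @export
detrend_moving_window <- function(data, value = "yield", year = "year",
                                  method = c("window", "linear"),
                                  relative = FALSE) {
  method <- match.arg(method)
  core <- function(y, yrs) {
    if (length(y) < 3) abort("need at least 3 years to de-trend")
    if (any(diff(yrs) != 1)) abort("years must be consecutive with no gaps")
    m <- if (method == "window") .detrend_window_means(y) else
      y - residuals(lm(y ~ yrs)) # fitted line
    if (relative) (y - m) / m else y - m
  }
  if (is.numeric(data) && is.null(dim(data))) {
    return(core(data, seq_along(data)))
  }
  assert_cols(data, c(value, year), "data")
  out <- dplyr::mutate(
    data,
    anomaly = {
      o <- order(.data[[year]])
      a <- core(.data[[value]][o], .data[[year]][o])
      a[order(o)]
    }
  )
  dplyr::ungroup(out)
}

#' Variance in one anomaly series explained by another
#'
#' Squared Pearson correlation and its t-test p-value. A negative correlation
#' still yields a positive R2; it is flagged so the sign is not silently lost.
#'
#' @param obs_anom,sim_anom numeric anomaly series of equal length (>= 4),
#'   finite, each with positive variance.
#' @return a one-row tibble: `r_squared`, `correlation`, `p_value`, `n`,
#'   `negative_correlation`.
#' @export
explained_variance <- function(obs_anom, sim_anom) {
  if (length(obs_anom) != length(sim_anom)) abort("series lengths differ")
  if (length(obs_anom) < 4) abort("need at least 4 points")
  if (!all(is.finite(obs_anom)) || !all(is.finite(sim_anom))) {
    abort("series must be finite")
  }
  if (var_pop(obs_anom) == 0 || var_pop(sim_anom) == 0) {
    abort("zero variance in an anomaly series")
  }
  ct <- cor.test(obs_anom, sim_anom, method = "pearson")
  r <- unname(ct$estimate)
  tibble::tibble(r_squared = r^2, correlation = r, p_value = ct$p.value,
                 n = length(obs_anom), negative_correlation = r < 0)
}

.case_table <- tibble::tibble(
  case = 1:6,
  treatment = c("T1", "T2", "T3", "T4", "T5", "T6"),
  mix = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
)

#' Evaluate simulation cases against observed yield series
#'
#' The six comparison cases map onto the treatments: cases 1-3 are the
#' irrigated runs (T1 mean-temperature only, T2 air-temperature heat, T3
#' canopy-temperature heat) aggregated over total production area, and cases
#' 4-6 are the water-limited runs (T4-T6) combined with their irrigated
#' counterparts as an area-weighted rainfed/irrigated mix. Observed and
#' simulated regional series are de-trended the same way and compared by
#' squared Pearson correlation, per pseudo-model.
#'
#' @param obs tibble `(region, year, yield)` of observed yields (a `crop`
#'   column is required when `table` contains several crops).
#' @param table a factorial table slice for a single scenario, GCM-analogue and
#'   CO2 arm (typically baseline/ambient).
#' @param areas a `crop_grid`.
#' @param cases integer subset of 1:6.
#' @param alpha significance level for counting models with significant
#'   correlations.
#' @param method de-trending method, `"window"` or `"linear"`.
#' @param relative use relative anomalies.
#' @return a `case_evaluation` object: `cases` (per region/case/model R2 and
#'   p-value) and `summary` (per region/case model count, significant count,
#'   and mean R2 over significant models — `NA` when none are significant).
#' @export
evaluate_cases <- function(obs, table, areas, cases = 1:6, alpha = 0.05,
                           method = c("window", "linear"), relative = FALSE) {
  method <- match.arg(method)
  assert_cols(obs, c("region", "year", "yield"), "obs")
  assert_cols(table, c("crop", "cell_id", "year", "treatment", "model", "yield"),
              "table")
  if (!all(cases %in% 1:6)) abort("`cases` must be a subset of 1:6")
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  for (col in c("scenario", "gcm", "co2_arm")) {
    if (col %in% names(table) && length(unique(table[[col]])) > 1) {
      abort(sprintf("`table` must be a single-%s slice", col))
    }
  }
  crops <- unique(table$crop)
  if (length(crops) > 1 && !"crop" %in% names(obs)) {
    abort("`obs` needs a `crop` column when `table` has several crops")
  }
  if (!"crop" %in% names(obs)) obs <- dplyr::mutate(obs, crop = crops)

  sim <- purrr::map_dfr(cases, function(cs) {
    row <- .case_table[.case_table$case == cs, ]
    wanted <- c(row$treatment, if (row$mix) .mix_pairs[[row$treatment]])
    slice <- dplyr::filter(table, .data$treatment %in% wanted)
    agg <- aggregate_yield(slice, areas, level = "region",
                           regime = if (row$mix) "mix" else "total")
    dplyr::mutate(agg, case = cs)
  })
  sim <- dplyr::rename(sim, region = "unit", sim_yield = "yield")

  if (!setequal(unique(obs$year), unique(sim$year))) {
    abort("observed and simulated series cover different years")
  }
  joined <- dplyr::inner_join(
    sim, dplyr::rename(obs, obs_yield = "yield"),
    by = c("crop", "region", "year")
  )
  n_expected <- length(unique(obs$year))
  detail <- dplyr::group_modify(
    dplyr::group_by(joined, .data$crop, .data$region, .data$case, .data$model),
    function(df, key) {
      if (nrow(df) != n_expected) {
        abort("observed and simulated series cover different years")
      }
      df <- df[order(df$year), ]
      explained_variance(
        detrend_moving_window(df$obs_yield, method = method, relative = relative),
        detrend_moving_window(df$sim_yield, method = method, relative = relative)
      )
    }
  )
  detail <- dplyr::ungroup(detail)
  detail$significant <- detail$p_value < alpha

  summary <- dplyr::summarise(
    dplyr::group_by(detail, .data$crop, .data$region, .data$case),
    n_models = dplyr::n(),
    n_significant = sum(.data$significant),
    mean_r2_significant = ifelse(sum(.data$significant) > 0,
                                 mean(.data$r_squared[.data$significant]),
                                 NA_real_),
    mean_r2_all = mean(.data$r_squared),
    .groups = "drop"
  )
  structure(list(cases = detail, summary = summary, alpha = alpha),
            class = "case_evaluation")
}

#' @export
print.case_evaluation <- function(x, ...) {
  cat("<case_evaluation> alpha =", x$alpha, "\n")
  print(x$summary, n = 20)
  invisible(x)
}
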