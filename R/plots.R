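#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar geom_col
#'   facet_grid facet_wrap labs position_dodge theme_bw
NULL

#' Plot a loss decomposition summary
#'
#' Ensemble medians with 10th-90th percentile bars per scenario, metric and
#' CO2 arm, faceted by crop and aggregation unit.
#'
#' @param object a `loss_decomposition`.
#' @param subset `"all"` or `"lowest_decile"`.
#' @param metrics which metrics to show.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot loss_decomposition
#' @export
autoplot.loss_decomposition <- function(object, subset = "all",
                                        metrics = c("potential_change",
                                                    "drought_loss_change",
                                                    "heat_loss_rainfed_change"),
                                        ...) {
  d <- dplyr::filter(object$summary, .data$subset == !!subset,
                     .data$metric %in% metrics,
                     .data$scenario != object$baseline)
  ggplot(d, aes(x = .data$scenario, y = .data$median, colour = .data$metric,
                shape = .data$co2_arm)) +
    geom_errorbar(aes(ymin = .data$p10, ymax = .data$p90),
                  position = position_dodge(width = 0.6), width = 0.2) +
    geom_point(position = position_dodge(width = 0.6), size = 2) +
    facet_grid(crop ~ unit) +
    labs(y = "change vs baseline (% or percentage points)",
         x = NULL, colour = "driver", shape = "CO2 arm") +
    theme_bw()
}

#' Plot variance-based sensitivity indices
#'
#' Main- and total-effect fractions per uncertainty factor (and crop).
#'
#' @param object a `sensitivity_indices` tibble.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot sensitivity_indices
#' @export
autoplot.sensitivity_indices <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("main_effect", "total_effect"),
                           names_to = "index", values_to = "value")
  p <- ggplot(d, aes(x = .data$factor, y = .data$value, fill = .data$index)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "fraction of variance") +
    theme_bw()
  if ("crop" %in% names(d)) p <- p + facet_wrap(~crop)
  p
}

#' Plot case-evaluation skill
#'
#' Mean R2 across significant models per comparison case and region.
#'
#' @param object a `case_evaluation`.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot case_evaluation
#' @export
autoplot.case_evaluation <- function(object, ...) {
  d <- object$summary
  p <- ggplot(d, aes(x = factor(.data$case), y = .data$mean_r2_all,
                     fill = factor(.data$case))) +
    geom_col(show.legend = FALSE) +
    labs(x = "comparison case", y = expression(mean ~ R^2)) +
    theme_bw()
  if ("crop" %in% names(d)) {
    p + facet_grid(crop ~ region)
  } else {
    p + facet_wrap(~region)
  }
}
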