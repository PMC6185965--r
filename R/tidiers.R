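#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for result objects
#'
#' `tidy()` returns the per-member detail table of a result object; `glance()`
#' returns a one-row summary of its extent.
#'
#' @param x a `loss_decomposition`, `case_evaluation` or `sensitivity_indices`
#'   object.
#' @param ... ignored.
#' @return a tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy loss_decomposition
#' @export
tidy.loss_decomposition <- function(x, ...) x$decomposition

#' @rdname tidiers
#' @method glance loss_decomposition
#' @export
glance.loss_decomposition <- function(x, ...) {
  d <- x$decomposition
  tibble::tibble(
    n_units = length(unique(d$unit)),
    n_scenarios = length(unique(d$scenario)),
    n_members = nrow(dplyr::distinct(d, .data$model, .data$gcm)),
    baseline = x$baseline
  )
}

#' @rdname tidiers
#' @method tidy case_evaluation
#' @export
tidy.case_evaluation <- function(x, ...) x$cases

#' @rdname tidiers
#' @method glance case_evaluation
#' @export
glance.case_evaluation <- function(x, ...) {
  tibble::tibble(
    n_regions = length(unique(x$summary$region)),
    n_cases = length(unique(x$summary$case)),
    alpha = x$alpha
  )
}

#' @rdname tidiers
#' @method tidy sensitivity_indices
#' @export
tidy.sensitivity_indices <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidiers
#' @method glance sensitivity_indices
#' @export
glance.sensitivity_indices <- function(x, ...) {
  tibble::tibble(
    n_factors = length(unique(x$factor)),
    var_y = attr(x, "var_y") %||% NA_real_
  )
}
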