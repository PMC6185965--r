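.check_balanced <- function(data, factors, what = "data") {
  counts <- dplyr::count(data, dplyr::across(dplyr::all_of(factors)))
  n_levels <- vapply(factors, function(f) length(unique(data[[f]])), numeric(1))
  if (nrow(counts) != prod(n_levels) || length(unique(counts$n)) != 1) {
    abort(sprintf("%s is not a balanced full factorial over (%s)",
                  what, paste(factors, collapse = ", ")))
  }
  invisible(TRUE)
}

.collapse_cells <- function(data, factors, response) {
  dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(factors))),
    .y = mean(.data[[response]]), .groups = "drop"
  )
}

.cond_mean_var <- function(data, by, response) {
  if (!length(by)) return(0)
  means <- dplyr::summarise(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(by))),
    .m = mean(.data[[response]]), .groups = "drop"
  )
  var_pop(means$.m)
}

#' Variance-based sensitivity indices over a full factorial
#'
#' Main effect of factor i: `ME_i = var(E[Y | X_i]) / var(Y)`; total effect:
#' `TS_i = 1 - var(E[Y | X_-i]) / var(Y)`, where `X_-i` is all declared factors
#' except i. Variances are population variances (divide by N) so the classical
#' identities hold exactly on finite balanced factorials: `0 <= ME_i <= TS_i
#' <= 1`, additive responses give `sum(ME) = 1` and `TS = ME`, and a pure
#' interaction gives `ME = 0`, `TS = 1`.
#'
#' Replicate rows within a factor-level cell (e.g. cells x years under each
#' scenario/model combination) are by default collapsed to their cell mean
#' before the decomposition, matching a design where the response is the
#' aggregate yield per factor combination; set `collapse_replicates = FALSE`
#' to keep replicate variation inside `var(Y)`.
#'
#' @param data a data frame holding the factorial.
#' @param factors character vector of factor column names (all declared
#'   factors; balance is checked over exactly these).
#' @param response response column name.
#' @param factor a single factor for the scalar index functions.
#' @param collapse_replicates collapse replicate rows to cell means first.
#' @return `main_effect_index()` / `total_effect_index()` return a single
#'   fraction; `sensitivity_indices()` returns a `sensitivity_indices` tibble
#'   `(factor, n_levels, main_effect, total_effect)` with `var(Y)` in the
#'   `var_y` attribute.
#' @name sensitivity
NULL

.prep_sensitivity <- function(data, factors, response, collapse_replicates) {
  assert_cols(data, c(factors, response), "data")
  .check_balanced(data, factors)
  if (collapse_replicates) {
    data <- .collapse_cells(data, factors, response)
    response <- ".y"
  }
  vy <- var_pop(data[[response]])
  if (vy == 0) abort("var(Y) is zero; nothing to decompose")
  list(data = data, response = response, var_y = vy)
}

#' @rdname sensitivity
#' @export
main_effect_index <- function(data, factor, factors, response = "yield",
                              collapse_replicates = TRUE) {
  if (!factor %in% factors) abort("`factor` must be one of `factors`")
  p <- .prep_sensitivity(data, factors, response, collapse_replicates)
  .cond_mean_var(p$data, factor, p$response) / p$var_y
}

#' @rdname sensitivity
#' @export
total_effect_index <- function(data, factor, factors, response = "yield",
                               collapse_replicates = TRUE) {
  if (!factor %in% factors) abort("`factor` must be one of `factors`")
  p <- .prep_sensitivity(data, factors, response, collapse_replicates)
  1 - .cond_mean_var(p$data, setdiff(factors, factor), p$response) / p$var_y
}

#' @rdname sensitivity
#' @export
sensitivity_indices <- function(data, factors, response = "yield",
                                collapse_replicates = TRUE) {
  p <- .prep_sensitivity(data, factors, response, collapse_replicates)
  out <- tibble::tibble(
    factor = factors,
    n_levels = vapply(factors, function(f) length(unique(p$data[[f]])),
                      numeric(1), USE.NAMES = FALSE),
    main_effect = vapply(factors, function(f) {
      .cond_mean_var(p$data, f, p$response) / p$var_y
    }, numeric(1), USE.NAMES = FALSE),
    total_effect = vapply(factors, function(f) {
      1 - .cond_mean_var(p$data, setdiff(factors, f), p$response) / p$var_y
    }, numeric(1), USE.NAMES = FALSE)
  )
  attr(out, "var_y") <- p$var_y
  class(out) <- c("sensitivity_indices", class(out))
  out
}

#' Uncertainty decomposition of EU-aggregate yields
#'
#' Applies the main/total-effect decomposition per crop over the declared
#' uncertainty factors (climate-model analogue, crop model, forcing pathway,
#' and whether CO2 fertilization is considered). Forcing pathways with an
#' incomplete set of climate-model analogues make the design unbalanced; the
#' default policy restricts to the analogues present under every pathway
#' (with a message), the alternative is to error.
#'
#' @param eu_yields tibble of EU-aggregate yields, one response value (or
#'   replicate set) per factor combination.
#' @param factors factor column names; defaults to
#'   `c("gcm", "model", "scenario", "co2_arm")`.
#' @param response response column name.
#' @param policy `"restrict"` or `"error"` for unbalanced designs.
#' @param collapse_replicates see [sensitivity_indices()].
#' @return a `sensitivity_indices` tibble with a `crop` column (when present)
#'   and a `var_y` column.
#' @export
decompose_uncertainty <- function(eu_yields,
                                  factors = c("gcm", "model", "scenario",
                                              "co2_arm"),
                                  response = "yield",
                                  policy = c("restrict", "error"),
                                  collapse_replicates = TRUE) {
  policy <- match.arg(policy)
  assert_cols(eu_yields, c(factors, response), "eu_yields")
  if (all(c("gcm", "scenario") %in% factors)) {
    by_scen <- split(eu_yields$gcm, eu_yields$scenario)
    common <- Reduce(intersect, lapply(by_scen, unique))
    if (!setequal(common, unique(eu_yields$gcm))) {
      if (policy == "error") {
        abort("unbalanced design: some pathways lack climate-model analogues")
      }
      message(sprintf(
        "restricting to climate-model analogues present in all pathways: %s",
        paste(common, collapse = ", ")))
      eu_yields <- dplyr::filter(eu_yields, .data$gcm %in% common)
    }
  }
  runner <- function(df) {
    sensitivity_indices(df, factors, response, collapse_replicates)
  }
  if ("crop" %in% names(eu_yields)) {
    out <- purrr::map_dfr(split(eu_yields, eu_yields$crop), function(df) {
      idx <- runner(df)
      dplyr::mutate(tibble::as_tibble(idx), crop = df$crop[1],
                    var_y = attr(idx, "var_y"), .before = 1)
    })
  } else {
    idx <- runner(eu_yields)
    out <- dplyr::mutate(tibble::as_tibble(idx), var_y = attr(idx, "var_y"))
  }
  class(out) <- c("sensitivity_indices", class(out))
  out
}
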