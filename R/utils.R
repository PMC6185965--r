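#' @importFrom rlang %||% abort .data
#' @importFrom stats rnorm runif rgamma median quantile cor.test lm residuals setNames
#' @importFrom utils head tail
NULL

# month index (1..12) for each day-of-year of the synthetic 365-day calendar
.month_of_doy <- rep(1:12, times = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# population variance (divide by N): keeps the finite-factorial Sobol identities exact
var_pop <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

#' Derive a reproducible sub-stream seed from a base seed and a key
#'
#' Deterministic polynomial string hash folded into a 31-bit integer. Used so that
#' every cell/scenario/stage draws from its own seeded stream while the whole
#' pipeline stays a pure function of one base seed.
#'
#' @param seed integer base seed.
#' @param ... key components (coerced to character).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
mix_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  for (key in unlist(lapply(list(...), as.character))) {
    for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# evaluate expr with a temporary RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
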