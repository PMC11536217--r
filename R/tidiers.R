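#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted rate surface
#'
#' @param x a `rate_surface`.
#' @param ... unused.
#' @return Tibble of log-scale basis coefficients (`term`, `estimate`).
#' @method tidy rate_surface
#' @export
tidy.rate_surface <- function(x, ...) {
  cf <- stats::coef(x$fit)
  tibble::tibble(term = names(cf), estimate = unname(cf))
}

#' @rdname tidy.rate_surface
#' @return For `glance`: one-row tibble with the measure, sex, fit
#'   dimensions and residual summaries (on the log scale).
#' @method glance rate_surface
#' @export
glance.rate_surface <- function(x, ...) {
  res <- stats::residuals(x$fit)
  tibble::tibble(measure = x$measure, sex = x$sex,
                 nobs = length(res),
                 df = length(stats::coef(x$fit)),
                 rss = sum(res^2),
                 sigma = stats::sigma(x$fit))
}

#' Tidy a fitted wave set
#'
#' @param x a `wave_set`.
#' @param ... unused.
#' @return Tibble with one row per wave: `wave`, `amplitude`, `mu`,
#'   `sigma`, `fwhm`, `start`, `end`.
#' @method tidy wave_set
#' @export
tidy.wave_set <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.wave_set
#' @method glance wave_set
#' @export
glance.wave_set <- function(x, ...) {
  series <- attr(x, "series")
  tibble::tibble(k = nrow(x), rss = attr(x, "rss"),
                 baseline = attr(x, "baseline"),
                 nobs = if (is.null(series)) NA_integer_ else nrow(series))
}

#' Tidy a projection result
#'
#' @param x an `idm_projection`.
#' @param ... unused.
#' @return The year-start aggregates as a plain tibble.
#' @method tidy idm_projection
#' @export
tidy.idm_projection <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.idm_projection
#' @method glance idm_projection
#' @export
glance.idm_projection <- function(x, ...) {
  tibble::tibble(n_scenarios = dplyr::n_distinct(x$scenario_id),
                 n_sexes = dplyr::n_distinct(x$sex),
                 year_min = min(x$year), year_max = max(x$year))
}
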