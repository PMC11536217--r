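#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted wave decomposition
#'
#' Weekly observations with the fitted Gaussian mixture and each wave's
#' FWHM interval shaded.
#'
#' @param object a `wave_set` from [fit_waves()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot wave_set
#' @export
autoplot.wave_set <- function(object, ...) {
  series <- attr(object, "series")
  grid <- tibble::tibble(
    time = seq(min(series$time), max(series$time), length.out = 600))
  grid$fit <- eval_waves(object, grid$time, attr(object, "baseline"))
  ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = .data$rate)) +
    ggplot2::geom_rect(data = tibble::as_tibble(object), inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -Inf, ymax = Inf),
                       fill = "grey85", alpha = 0.5) +
    ggplot2::geom_point(size = 0.6, colour = "grey30") +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "firebrick") +
    ggplot2::labs(x = "year", y = "weekly incidence per 100,000",
                  title = sprintf("%d-wave Gaussian decomposition", nrow(object)))
}

#' Plot projected prevalence by scenario
#'
#' Year-start prevalence trajectories per sex, one line per scenario.
#'
#' @param object an `idm_projection`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot idm_projection
#' @export
autoplot.idm_projection <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$year, y = .data$prevalence_pct,
                               group = .data$scenario_id,
                               colour = factor(.data$scenario_id))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "year", y = "prevalence (%)", colour = "scenario")
}

#' Plot a rate surface as age profiles over selected years
#'
#' @param object a `rate_surface`.
#' @param years calendar years to draw (default five across the domain).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot rate_surface
#' @export
autoplot.rate_surface <- function(object, years = NULL, ...) {
  if (is.null(years))
    years <- round(seq(object$time_domain[1], object$time_domain[2],
                       length.out = 5))
  df <- tidyr::expand_grid(
    age = seq(object$age_domain[1], object$age_domain[2], by = 1),
    year = years)
  df$value <- eval_rate(object, df$age, df$year)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$value,
                                   colour = factor(.data$year))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (years)", y = object$measure, colour = "year")
}

#' Plot an incidence-shock function
#'
#' @param shock a [build_shock()] result.
#' @param from,to time range (defaults to the shock's own support padded
#'   by a quarter year).
#' @return A ggplot of the relative incidence increase over time.
#' @export
plot_shock <- function(shock, from = NULL, to = NULL) {
  nd <- attr(shock, "nodes")
  if (!nrow(nd)) stop("baseline shock is identically zero", call. = FALSE)
  if (is.null(from)) from <- min(nd$t0) - 0.25
  if (is.null(to)) to <- max(nd$t3) + 0.25
  df <- tibble::tibble(time = seq(from, to, length.out = 800))
  df$A <- shock(df$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$A)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "year", y = "relative incidence increase A(t)")
}
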