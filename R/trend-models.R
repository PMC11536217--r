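#' Fit a smooth age-by-time rate surface
#'
#' Fits an additive natural-cubic-spline model on the log scale,
#' `log(val) ~ ns(age) + ns(year)`, to age-, year-specific rate or
#' proportion estimates.  The natural-spline boundary property makes the
#' log-scale surface continue linearly beyond the last calendar year, which
#' is how historical trends are extrapolated into projection years.  Age is
#' never extrapolated.  An optional tensor-product interaction is available
#' for surfaces whose age profile changes shape over time.
#'
#' @param data data frame with columns `age`, `year`, `val` (one sex, one
#'   measure).  Values must be positive; zeros are lifted to `floor`.
#' @param measure one of `"incidence"`, `"prevalence"`, `"mortality_all"`,
#'   `"mortality_susceptible"`, `"mortality_diseased"`.  Prevalence
#'   evaluations are clipped to at most 1.
#' @param age_knots,year_knots interior knot positions.  Defaults: every
#'   10 years of age, every 5 calendar years, clipped to the data range.
#' @param interaction add age:year tensor-product spline terms.
#' @param floor value replacing zeros before the log transform.
#' @param sex optional label stored with the fit.
#' @return A `rate_surface` object; evaluate it with [eval_rate()].
#' @export
fit_rate_surface <- function(data, measure,
                             age_knots = NULL, year_knots = NULL,
                             interaction = FALSE, floor = 1e-8,
                             sex = NA_character_) {
  stopifnot(all(c("age", "year", "val") %in% names(data)))
  measure <- match.arg(measure, c("incidence", "prevalence", "mortality_all",
                                  "mortality_susceptible", "mortality_diseased"))
  if (any(data$val < 0)) stop("rate values must be nonnegative", call. = FALSE)
  if (dplyr::n_distinct(data$age) < 2 || dplyr::n_distinct(data$year) < 2)
    stop("need at least 2 distinct ages and 2 distinct years", call. = FALSE)

  age_rng <- range(data$age)
  year_rng <- range(data$year)
  default_knots <- function(rng, by) {
    k <- seq(ceiling(rng[1] / by) * by, rng[2], by = by)
    k[k > rng[1] & k < rng[2]]
  }
  if (is.null(age_knots)) age_knots <- default_knots(age_rng, 10)
  if (is.null(year_knots)) year_knots <- default_knots(year_rng, 5)
  if (dplyr::n_distinct(data$age) <= length(age_knots) + 1)
    stop("too many age knots for ", dplyr::n_distinct(data$age),
         " distinct ages", call. = FALSE)
  if (dplyr::n_distinct(data$year) <= length(year_knots) + 1)
    stop("too many year knots for ", dplyr::n_distinct(data$year),
         " distinct years", call. = FALSE)

  df <- data.frame(age = data$age, year = data$year,
                   logval = log(pmax(data$val, floor)))
  form <- if (interaction) {
    logval ~ splines::ns(age, knots = age_knots, Boundary.knots = age_rng) *
      splines::ns(year, knots = year_knots, Boundary.knots = year_rng)
  } else {
    logval ~ splines::ns(age, knots = age_knots, Boundary.knots = age_rng) +
      splines::ns(year, knots = year_knots, Boundary.knots = year_rng)
  }
  env <- environment()
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    dim_hint <- if (interaction) "age:year interaction" else "age or year"
    stop("rank-deficient spline basis (", dim_hint,
         "): reduce the number of knots", call. = FALSE)
  }
  structure(
    list(fit = fit, measure = measure, sex = sex,
         age_knots = age_knots, year_knots = year_knots,
         age_domain = age_rng, time_domain = year_rng,
         interaction = interaction, floor = floor),
    class = "rate_surface")
}

#' Evaluate a rate surface
#'
#' Exponentiates the fitted log-scale spline at `(age, time)`.  Calendar
#' time beyond the fitted domain follows the natural spline's linear
#' (log-scale) continuation; age outside the fitted domain is an error.
#' Prevalence surfaces are clipped to at most 1.
#'
#' @param surface a `rate_surface` from [fit_rate_surface()].
#' @param age,time numeric vectors (recycled against each other).
#' @return Rates (per person-year) or proportions.
#' @export
eval_rate <- function(surface, age, time) {
  stopifnot(inherits(surface, "rate_surface"))
  n <- max(length(age), length(time))
  age <- rep_len(age, n); time <- rep_len(time, n)
  if (any(age < surface$age_domain[1] - 1e-9) ||
      any(age > surface$age_domain[2] + 1e-9))
    stop("age outside the fitted domain [", surface$age_domain[1], ", ",
         surface$age_domain[2], "]; age is not extrapolated", call. = FALSE)
  val <- exp(unname(stats::predict(surface$fit,
                                   newdata = data.frame(age = age, year = time))))
  if (surface$measure == "prevalence") val <- pmin(val, 1)
  val
}

#' @export
print.rate_surface <- function(x, ...) {
  cat("<rate_surface>", x$measure,
      if (!is.na(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  age domain  ", paste(x$age_domain, collapse = "-"),
      " knots: ", paste(x$age_knots, collapse = ", "), "\n", sep = "")
  cat("  time domain ", paste(x$time_domain, collapse = "-"),
      " knots: ", paste(x$year_knots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct the two-group mortality model
#'
#' Splits an overall mortality surface `m_all` into mortality among the
#' susceptible (`m0`) and among the diseased (`m1`) by solving, at every
#' `(age, time)`,
#' \deqn{m_{all} = p\,m_1 + (1 - p)\,m_0, \qquad m_1 = RR(t)\, m_0,}
#' where `p` is the prevalence and the mortality-risk ratio declines
#' linearly over calendar time, floored at 1:
#' \eqn{RR(t) = \max(1,\; rr_0 - d\,(t - t_{ref}))}.  A declining ratio
#' makes mortality improve faster in the diseased group, while overall
#' mortality is preserved exactly.
#'
#' @param m_all overall mortality: a `rate_surface` or a vectorised
#'   function `f(age, time)`.
#' @param prev prevalence: a `rate_surface` or function `f(age, time)`
#'   with values in `[0, 1)`.
#' @param rr0 mortality-risk ratio at the reference time (default 1.4).
#' @param rr_decline linear decline of the ratio per year (default 0.01).
#' @param reference_time decimal year at which the ratio equals `rr0`.
#' @return A `mortality_model` with elements `m0` and `m1`, each a
#'   vectorised function of `(age, time)`, plus `rr(time)`.
#' @export
build_mortality <- function(m_all, prev, rr0 = 1.4, rr_decline = 0.01,
                            reference_time = 2019) {
  if (rr0 < 1) stop("rr0 must be >= 1", call. = FALSE)
  as_fun <- function(x) if (is.function(x)) x else function(age, time) eval_rate(x, age, time)
  m_all_f <- as_fun(m_all)
  prev_f <- as_fun(prev)
  rr <- function(time) pmax(1, rr0 - rr_decline * (time - reference_time))
  m0 <- function(age, time) {
    p <- prev_f(age, time)
    if (any(p >= 1)) stop("prevalence of 1: m0 undefined", call. = FALSE)
    m_all_f(age, time) / (1 + p * (rr(time) - 1))
  }
  m1 <- function(age, time) rr(time) * m0(age, time)
  structure(list(m0 = m0, m1 = m1, rr = rr, rr0 = rr0,
                 rr_decline = rr_decline, reference_time = reference_time),
            class = "mortality_model")
}

#' @export
print.mortality_model <- function(x, ...) {
  cat("<mortality_model> RR(t) = max(1, ", x$rr0, " - ", x$rr_decline,
      " * (t - ", x$reference_time, "))\n", sep = "")
  invisible(x)
}

#' Derive overall mortality from cohort shrinkage of a population pyramid
#'
#' With migration assumed zero, the only way a cohort shrinks from one year
#' to the next is death, so the overall mortality rate is the negative log
#' survival of each cohort:
#' \eqn{m_{all}(a, y) = -\log(N(a{+}1, y{+}1) / N(a, y))}.
#' Returned as a step-function lookup over single-year cells; times beyond
#' the table's last transition reuse the last available year (age profiles
#' of mortality change slowly relative to the projection horizon).
#'
#' @param pyramid tibble with columns `age`, `year`, `count` (one sex).
#' @return A vectorised function `f(age, time)`.
#' @export
mortality_from_pyramid <- function(pyramid) {
  stopifnot(all(c("age", "year", "count") %in% names(pyramid)))
  tab <- pyramid |>
    dplyr::arrange(.data$age, .data$year) |>
    dplyr::group_by(.data$age) |>
    dplyr::mutate(next_count = dplyr::lead(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::inner_join(
      pyramid |> dplyr::transmute(age = .data$age - 1L, year = .data$year - 1L,
                                  succ = .data$count),
      by = c("age", "year")) |>
    dplyr::filter(.data$count > 0, .data$succ > 0) |>
    dplyr::mutate(m = pmax(0, -log(.data$succ / .data$count)))
  ages <- sort(unique(tab$age))
  years <- sort(unique(tab$year))
  grid <- matrix(NA_real_, length(ages), length(years),
                 dimnames = list(ages, years))
  grid[cbind(match(tab$age, ages), match(tab$year, years))] <- tab$m
  # oldest modelled age has no successor cell; carry the last age forward
  for (j in seq_along(years))
    grid[, j] <- na_locf(grid[, j])
  function(age, time) {
    ai <- pmin(pmax(findInterval(floor(age), ages), 1), length(ages))
    yi <- pmin(pmax(findInterval(floor(time), years), 1), length(years))
    grid[cbind(ai, yi)]
  }
}

# last-observation-carried-forward for a numeric vector (head NAs -> first value)
na_locf <- function(x) {
  idx <- cumsum(!is.na(x))
  filled <- x[!is.na(x)][pmax(idx, 1)]
  filled
}
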