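#' Configuration for the synthetic-data generator
#'
#' Bundles every ground-truth parameter of the synthetic inputs: the
#' age-time transition-rate functions of the illness-death model, the
#' population pyramid, and the weekly epidemic series composed of Gaussian
#' waves.  The defaults describe a large European-style population with a
#' common, remitting disorder that is about twice as frequent in women as
#' in men, observed annually over 1990-2019 on single-year ages 0-95, and
#' an epidemic of seven infection waves over 2020-2022.
#'
#' @param seed integer seed controlling all randomness.
#' @param age_max oldest modelled age (years).
#' @param years_history calendar interval of the historical annual grid.
#' @param years_projection calendar interval of the projection horizon.
#' @param wave_params tibble with columns `amplitude` (cases per 100,000
#'   per week), `mu` (decimal-year centre, strictly increasing) and `sigma`
#'   (years, positive); one row per wave.
#' @param noise_sd relative (lognormal) noise scale of the weekly series.
#' @param base_rates list of ground-truth rate parameters; see Details.
#'
#' @details `base_rates` fields (all rates per person-year):
#'   * `inc_peak_age`, `inc_quad`: the log-incidence is quadratic in age,
#'     peaking at `inc_peak_age` with curvature `-inc_quad`;
#'   * `inc_level`: named incidence at the peak age in 2005, per sex;
#'   * `inc_trend`: log-linear calendar slope of incidence;
#'   * `mort_a`, `mort_b`: Gompertz overall-ish mortality
#'     `exp(mort_a + mort_b * age)` among the susceptible;
#'   * `mort_trend`: log-linear calendar slope of mortality;
#'   * `rr0`, `rr_decline`, `rr_ref`: mortality-risk ratio of the diseased,
#'     `RR(t) = max(1, rr0 - rr_decline (t - rr_ref))`;
#'   * `remission`: constant remission rate (per year).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         age_max = 95L,
                         years_history = c(1990, 2019),
                         years_projection = c(2019, 2030),
                         wave_params = default_waves(),
                         noise_sd = 0.05,
                         base_rates = list()) {
  defaults <- list(
    inc_peak_age = 25, inc_quad = 0.002,
    inc_level = c(female = 0.009, male = 0.005),
    inc_trend = -0.003,
    mort_a = -9.9, mort_b = 0.09, mort_trend = -0.005,
    rr0 = 1.4, rr_decline = 0.01, rr_ref = 2019,
    remission = 0.05)
  base_rates <- utils::modifyList(defaults, base_rates)
  stopifnot(age_max >= 1, noise_sd >= 0,
            all(wave_params$sigma > 0),
            !is.unsorted(wave_params$mu, strictly = TRUE))
  structure(list(seed = as.integer(seed), age_max = as.integer(age_max),
                 years_history = years_history,
                 years_projection = years_projection,
                 wave_params = wave_params, noise_sd = noise_sd,
                 base_rates = base_rates),
            class = "synth_config")
}

#' Default seven-wave layout of the synthetic epidemic series
#'
#' Seven Gaussian waves spanning early 2020 to late 2022 with centres
#' separated by more than one FWHM, echoing the shape of the German
#' COVID-19 weekly incidence record (small first waves, dominant waves in
#' winter 2021/22).
#'
#' @return Tibble with `amplitude`, `mu`, `sigma`.
#' @export
default_waves <- function() {
  tibble::tibble(
    amplitude = c(35, 160, 110, 85, 900, 1400, 450),
    mu = c(2020.23, 2020.95, 2021.30, 2021.70, 2021.95, 2022.25, 2022.75),
    sigma = c(0.055, 0.070, 0.060, 0.045, 0.050, 0.080, 0.070))
}

# ground-truth rate functions implied by a synth_config, per sex
truth_rates <- function(config, sex) {
  br <- config$base_rates
  level <- br$inc_level[[sex]]
  peak <- br$inc_peak_age
  list(
    incidence = function(age, time)
      level * exp(-br$inc_quad * (age - peak)^2 + br$inc_trend * (time - 2005)),
    m0 = function(age, time)
      exp(br$mort_a + br$mort_b * age + br$mort_trend * (time - 2005)),
    rr = function(time) pmax(1, br$rr0 - br$rr_decline * (time - br$rr_ref)),
    m1 = function(age, time)
      pmax(1, br$rr0 - br$rr_decline * (time - br$rr_ref)) *
        exp(br$mort_a + br$mort_b * age + br$mort_trend * (time - 2005)),
    remission = function(age, time)
      rep(br$remission, length.out = max(length(age), length(time))))
}

#' Generate a model-consistent synthetic history for one sex
#'
#' Produces annual age-specific incidence, prevalence and two-group
#' mortality over the historical interval, where the prevalence surface is
#' exactly the forward simulation of the illness-death prevalence-odds
#' recursion under the ground-truth rates, starting from the
#' no-differential-mortality equilibrium prevalence
#' `p0 = i / (i + rho)` in the first year.  Feeding the returned
#' `(p, i, m0, m1)` back into [estimate_remission()] therefore recovers the
#' ground-truth remission schedule to machine precision.
#'
#' @param config a [synth_config()].
#' @param sex `"female"` or `"male"`.
#' @param tau step length of the annual grid (default 1 year).
#' @return A list: `rates` (long tibble `measure`, `sex`, `age`, `year`,
#'   `val` with measures incidence, prevalence, mortality_susceptible,
#'   mortality_diseased), `remission` (tibble `age`, `year`, `r` of the
#'   per-step ground truth) and `truth` (the rate functions).
#' @export
gen_consistent_history <- function(config, sex = c("female", "male"), tau = 1) {
  sex <- match.arg(sex)
  tr <- truth_rates(config, sex)
  ages <- 0:config$age_max
  years <- seq(config$years_history[1], config$years_history[2], by = tau)
  r_step <- config$base_rates$remission * tau

  i0 <- tr$incidence(ages, years[1])
  check_step_rates(i0, tr$m0(ages, years[1]), tr$m1(ages, years[1]),
                   r_step, tau)
  p <- matrix(NA_real_, length(ages), length(years))
  rho <- config$base_rates$remission
  # stated initial prevalence: the no-differential-mortality equilibrium
  # i/(i + rho); without remission that has no finite solution, so fall
  # back to the (small) incidence itself as the starting level
  p[, 1] <- if (rho > 0) i0 / (i0 + rho) else pmin(i0, 0.99)
  pi_k <- p[, 1] / (1 - p[, 1])
  for (j in seq_len(length(years) - 1)) {
    yr <- years[j]
    pi_k <- step_odds(pi_k,
                      i = tr$incidence(ages, yr),
                      m0 = tr$m0(ages, yr),
                      m1 = tr$m1(ages, yr),
                      r = r_step, tau = tau)
    p[, j + 1] <- pi_k / (1 + pi_k)
  }
  grid <- tidyr::expand_grid(year = years, age = ages) |>
    dplyr::arrange(.data$age, .data$year)
  long <- dplyr::bind_rows(
    grid |> dplyr::mutate(measure = "incidence",
                          val = tr$incidence(.data$age, .data$year)),
    grid |> dplyr::mutate(measure = "prevalence",
                          val = as.vector(t(p))),
    grid |> dplyr::mutate(measure = "mortality_susceptible",
                          val = tr$m0(.data$age, .data$year)),
    grid |> dplyr::mutate(measure = "mortality_diseased",
                          val = tr$m1(.data$age, .data$year))) |>
    dplyr::transmute(measure = .data$measure, sex = sex,
                     age = .data$age, year = .data$year, val = .data$val)
  remission <- grid |>
    dplyr::transmute(age = .data$age, year = .data$year, r = r_step)
  list(rates = long, remission = remission, truth = tr, tau = tau)
}

#' Generate a cohort-consistent population projection
#'
#' Builds a pyramid by ageing a base-year population forward with the
#' ground-truth overall mortality (no migration): each cohort shrinks by
#' its survival probability and the year's births enter at age 0.  Births
#' fluctuate around a constant level with seeded lognormal noise.
#'
#' @param config a [synth_config()].
#' @param base_count age-0 count in the base year.
#' @param age_slope exponential decline of the base-year age structure.
#' @param births_level mean annual births per sex.
#' @param births_sd relative fluctuation of annual births (lognormal).
#' @return A list: `pyramid` (tibble `age`, `sex`, `year`, `count`) and
#'   `births` (tibble `sex`, `year`, `births`), covering the history and
#'   projection intervals.
#' @export
gen_population <- function(config, base_count = 4e5, age_slope = 0.008,
                           births_level = 3.8e5, births_sd = 0.02) {
  ages <- 0:config$age_max
  years <- seq(config$years_history[1], config$years_projection[2] + 1)
  out <- vector("list", 2)
  for (sx in c("female", "male")) {
    set.seed(config$seed + if (sx == "female") 0L else 1L)
    tr <- truth_rates(config, sx)
    # crude overall mortality: susceptible-group Gompertz (prevalence-weighted
    # correction is second order for pyramid purposes)
    births <- births_level * exp(stats::rnorm(length(years), 0, births_sd))
    N <- matrix(0, length(ages), length(years))
    N[, 1] <- base_count * exp(-age_slope * ages)
    for (j in seq_len(length(years) - 1)) {
      surv <- exp(-tr$m0(ages, years[j]))
      N[2:length(ages), j + 1] <- N[seq_len(length(ages) - 1), j] *
        surv[seq_len(length(ages) - 1)]
      N[1, j + 1] <- births[j + 1]
    }
    out[[if (sx == "female") 1 else 2]] <- list(
      pyramid = tidyr::expand_grid(age = ages, year = years) |>
        dplyr::mutate(sex = sx, count = as.vector(t(N))),
      births = tibble::tibble(sex = sx, year = years, births = births))
  }
  list(
    pyramid = dplyr::bind_rows(out[[1]]$pyramid, out[[2]]$pyramid) |>
      dplyr::select("age", "sex", "year", "count"),
    births = dplyr::bind_rows(out[[1]]$births, out[[2]]$births))
}

#' Generate a weekly epidemic incidence series with known waves
#'
#' Evaluates the configured Gaussian wave mixture at ISO-week midpoints
#' from the first week of 2020 through the last week of 2022 and applies
#' multiplicative lognormal noise of scale `noise_sd` (truncated at zero,
#' trivially satisfied by the lognormal).
#'
#' @param config a [synth_config()].
#' @return A list: `series` (tibble `year_week` \code{"YYYY-Www"}, `time`
#'   decimal-year midpoint, `rate` cases per 100,000 per week) and `waves`
#'   (the ground-truth wave tibble).
#' @export
gen_covid_series <- function(config) {
  stopifnot(nrow(config$wave_params) >= 1)
  wk <- iso_week_grid(2020, 2022)
  clean <- eval_waves(config$wave_params, wk$time)
  set.seed(config$seed + 2L)
  noise <- if (config$noise_sd > 0)
    exp(stats::rnorm(nrow(wk), 0, config$noise_sd)) else 1
  series <- wk |> dplyr::mutate(rate = pmax(0, clean * noise))
  list(series = series, waves = config$wave_params)
}

# all ISO weeks of the given years, with decimal-year midpoints
iso_week_grid <- function(from_year, to_year) {
  purrr::map_dfr(from_year:to_year, function(y) {
    n <- iso_weeks_in_year(y)
    tibble::tibble(year_week = sprintf("%d-W%02d", y, seq_len(n)))
  }) |>
    dplyr::mutate(time = iso_week_midpoint(.data$year_week))
}

iso_weeks_in_year <- function(year) {
  # a year has 53 ISO weeks iff Jan 1 or Dec 31 falls on a Thursday
  thu <- function(d) format(d, "%u") == "4"
  if (thu(as.Date(sprintf("%d-01-01", year))) ||
      thu(as.Date(sprintf("%d-12-31", year)))) 53L else 52L
}
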