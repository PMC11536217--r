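#' Initial compartment state from a prevalence surface and a pyramid
#'
#' Splits each age's population count at the start year into diseased
#' `C = p N` and susceptible `S = (1 - p) N`.
#'
#' @param prev prevalence: a `rate_surface` or vectorised `f(age, time)`
#'   with values in `[0, 1]` (exactly 1 anywhere is an error).
#' @param pyramid tibble `age`, `year`, `count` for one sex.
#' @param start_year calendar year the state describes (must be in the
#'   pyramid).
#' @param sex label stored with the state.
#' @return A [compartment_state()].
#' @export
initialise_states <- function(prev, pyramid, start_year, sex = "female") {
  p_f <- if (is.function(prev)) prev else function(a, t) eval_rate(prev, a, t)
  n <- pyramid |>
    dplyr::filter(.data$year == start_year) |>
    dplyr::arrange(.data$age)
  if (!nrow(n)) stop("pyramid does not cover year ", start_year, call. = FALSE)
  p <- p_f(n$age, start_year)
  if (any(p > 1)) stop("prevalence above 1", call. = FALSE)
  compartment_state(S = (1 - p) * n$count, C = p * n$count,
                    time = start_year, sex = sex)
}

#' Prepare all projection inputs from history, population and config
#'
#' Runs the estimation half of the pipeline for both sexes: fits the
#' incidence and prevalence trend surfaces to the historical rate table,
#' derives overall mortality from cohort shrinkage of the pyramid, builds
#' the two-group mortality model with the declining risk ratio, estimates
#' the remission schedule by inverting the prevalence-odds recursion on
#' the annual history grid (held constant at its last estimated age
#' profile thereafter), draws the initial compartments from the pyramid,
#' and precomputes every rate on the weekly projection grid.
#'
#' @param rates long tibble `measure`, `sex`, `age`, `year`, `val`
#'   containing at least `incidence` and `prevalence` for both sexes.
#' @param pop list with `pyramid` and `births` (see [read_population()]).
#' @param horizon projection interval in decimal years (default
#'   `c(2019, 2031)`, reporting year starts through 2030).
#' @param steps_per_year weekly by default (52).
#' @param rr0,rr_decline,reference_time mortality-risk-ratio model
#'   (see [build_mortality()]).
#' @param age_knots,year_knots passed to [fit_rate_surface()].
#' @return A `projection_prep` list with per-sex rate arrays on the
#'   age-by-week grid, initial states and birth schedules.
#' @export
prepare_projection <- function(rates, pop, horizon = c(2019, 2031),
                               steps_per_year = 52L,
                               rr0 = 1.4, rr_decline = 0.01,
                               reference_time = 2019,
                               age_knots = NULL, year_knots = NULL) {
  stopifnot(horizon[2] > horizon[1])
  spy <- as.integer(steps_per_year)
  tau <- 1 / spy
  n_steps <- as.integer(round((horizon[2] - horizon[1]) * spy))
  t_grid <- horizon[1] + (seq_len(n_steps) - 1L) / spy
  sexes <- sort(unique(rates$sex))

  per_sex <- purrr::map(sexes, function(sx) {
    hist_sx <- dplyr::filter(rates, .data$sex == sx)
    pyr_sx <- dplyr::filter(pop$pyramid, .data$sex == sx)
    ages <- sort(unique(pyr_sx$age))

    inc <- fit_rate_surface(dplyr::filter(hist_sx, .data$measure == "incidence"),
                            "incidence", age_knots, year_knots, sex = sx)
    prv <- fit_rate_surface(dplyr::filter(hist_sx, .data$measure == "prevalence"),
                            "prevalence", age_knots, year_knots, sex = sx)
    m_all <- mortality_from_pyramid(pyr_sx)
    mort <- build_mortality(m_all, prv, rr0 = rr0, rr_decline = rr_decline,
                            reference_time = reference_time)

    # remission from the annual history grid, via odds inversion
    p_tab <- hist_sx |>
      dplyr::filter(.data$measure == "prevalence") |>
      dplyr::transmute(age = .data$age, time = .data$year,
                       p = pmin(.data$val, 1 - 1e-12))
    r_est <- estimate_remission(
      p_tab,
      i = function(a, t) eval_rate(inc, a, t),
      m0 = mort$m0, m1 = mort$m1, tau = 1)
    # hold the last estimated age profile constant over the projection
    r_profile <- r_est |>
      dplyr::filter(.data$time == max(.data$time)) |>
      dplyr::arrange(.data$age)
    rho <- rep(NA_real_, length(ages))  # remission rate per year, by age
    rho[match(r_profile$age, ages)] <- r_profile$r
    if (all(is.na(rho))) rho[] <- 0 else rho <- na_locf(rho)
    rho[is.na(rho)] <- 0

    init <- initialise_states(prv, pyr_sx, horizon[1], sex = sx)

    arr <- function(f) outer(ages, t_grid, f)
    list(sex = sx, ages = ages, incidence = inc, prevalence = prv,
         mortality = mort, remission_rate = rho, init = init,
         i_base = arr(function(a, t) eval_rate(inc, a, t)),
         m0 = arr(mort$m0), m1 = arr(mort$m1),
         births = dplyr::filter(pop$births, .data$sex == sx))
  })
  names(per_sex) <- sexes
  structure(list(per_sex = per_sex, horizon = horizon, tau = tau,
                 steps_per_year = spy, t_grid = t_grid),
            class = "projection_prep")
}

#' Run one scenario projection
#'
#' Steps the illness-death model weekly from the start to the end of the
#' horizon for each sex, with the scenario's incidence shock multiplying
#' the baseline incidence, ageing all cohorts (and admitting births) at
#' every calendar year boundary, and recording year-start aggregates.
#'
#' @param prep a [prepare_projection()] result.
#' @param params one row of [scenario_grid()].
#' @param waves fitted `wave_set` (ignored for the baseline scenario).
#' @param shape shock shape, see [build_shock()].
#' @param keep_trajectory also return the full age-resolved year-start
#'   states.
#' @return An `idm_projection`: tibble `scenario_id`, `sex`, `year`,
#'   `cases`, `population`, `prevalence_pct` (year-start values), with the
#'   trajectory in `attr(, "trajectory")` when requested.
#' @export
run_projection <- function(prep, params, waves = NULL,
                           shape = c("trapezoid", "triangle"),
                           keep_trajectory = FALSE) {
  stopifnot(inherits(prep, "projection_prep"))
  shape <- match.arg(shape)
  shock <- build_shock(params, waves, shape)
  mult <- 1 + shock(prep$t_grid)
  spy <- prep$steps_per_year
  tau <- prep$tau
  rows <- list(); traj <- list()

  for (ps in prep$per_sex) {
    S <- ps$init$S; C <- ps$init$C
    clamped <- 0; total0 <- sum(S + C)
    r_step <- ps$remission_rate * tau
    births <- stats::setNames(ps$births$births, ps$births$year)
    for (k in seq_along(prep$t_grid)) {
      t_k <- prep$t_grid[k]
      if (k > 1 && (k - 1) %% spy == 0) {  # calendar year boundary
        b_y <- births[[as.character(round(t_k))]]
        n <- length(S)
        S <- c(b_y, S[-n]); C <- c(0, C[-n])
      }
      if ((k - 1) %% spy == 0) {
        yr <- round(t_k)
        rows[[length(rows) + 1]] <- tibble::tibble(
          scenario_id = params$scenario_id, sex = ps$sex, year = yr,
          cases = sum(C), population = sum(S + C),
          prevalence_pct = 100 * sum(C) / sum(S + C))
        if (keep_trajectory)
          traj[[length(traj) + 1]] <- tibble::tibble(
            scenario_id = params$scenario_id, sex = ps$sex, year = yr,
            age = ps$ages, S = S, C = C)
      }
      st <- step_sc(S, C, ps$i_base[, k] * mult[k],
                    ps$m0[, k], ps$m1[, k], r_step, tau)
      S <- st$S; C <- st$C; clamped <- clamped + st$clamped
    }
    if (clamped > 1e-4 * total0)
      stop("more than 0.01% of the population mass was clamped at zero in ",
           "scenario ", params$scenario_id, ", sex ", ps$sex,
           ": reduce the step length", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (keep_trajectory) attr(out, "trajectory") <- dplyr::bind_rows(traj)
  class(out) <- c("idm_projection", class(out))
  out
}

#' Run every scenario of a grid
#'
#' @param prep a [prepare_projection()] result.
#' @param waves fitted `wave_set`.
#' @param scenarios scenario tibble (default the full [scenario_grid()]).
#' @inheritParams run_projection
#' @return An `idm_projection` tibble covering all scenarios.
#' @export
run_scenario_grid <- function(prep, waves, scenarios = scenario_grid(),
                              shape = c("trapezoid", "triangle")) {
  shape <- match.arg(shape)
  out <- purrr::map_dfr(seq_len(nrow(scenarios)), function(j)
    run_projection(prep, scenarios[j, ], waves, shape))
  class(out) <- c("idm_projection", class(out))
  out
}

#' Summarise projections for selected scenarios and years
#'
#' @param results an `idm_projection` tibble.
#' @param years calendar years to report (default the headline years
#'   2020, 2021, 2023 and 2030).
#' @param scenarios scenario ids to report (default all present).
#' @return Long tibble `scenario_id`, `sex`, `year`, `cases`,
#'   `cases_millions` (2 d.p.), `prevalence_pct` (2 d.p.).
#' @export
summarise_projection <- function(results, years = c(2020, 2021, 2023, 2030),
                                 scenarios = NULL) {
  if (is.null(scenarios)) scenarios <- unique(results$scenario_id)
  missing_sc <- setdiff(scenarios, results$scenario_id)
  if (length(missing_sc))
    stop("unknown scenario id(s): ", paste(missing_sc, collapse = ", "),
         call. = FALSE)
  missing_yr <- setdiff(years, results$year)
  if (length(missing_yr))
    stop("year(s) outside the projected horizon: ",
         paste(missing_yr, collapse = ", "), call. = FALSE)
  results |>
    dplyr::filter(.data$scenario_id %in% scenarios, .data$year %in% years) |>
    dplyr::transmute(scenario_id = .data$scenario_id, sex = .data$sex,
                     year = .data$year, cases = .data$cases,
                     cases_millions = round(.data$cases / 1e6, 2),
                     prevalence_pct = round(.data$prevalence_pct, 2)) |>
    dplyr::arrange(.data$scenario_id, .data$sex, .data$year)
}
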