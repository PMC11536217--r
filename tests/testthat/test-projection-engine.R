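test_that("initial states split the pyramid by prevalence", {
  pyr <- tidyr::expand_grid(age = 0:95, year = 2019) |>
    dplyr::mutate(count = 1000)
  st0 <- initialise_states(function(a, t) rep(0, length(a)), pyr, 2019)
  expect_equal(st0$C, rep(0, 96))
  expect_equal(st0$S, rep(1000, 96))

  st <- initialise_states(function(a, t) rep(0.1, length(a)), pyr, 2019)
  expect_equal(st$C, rep(100, 96))
  expect_equal(st$S, rep(900, 96))

  pyr_f <- dplyr::filter(fix_pop$pyramid, sex == "female")
  stf <- initialise_states(fix_prep$per_sex$female$prevalence, pyr_f, 2019,
                           sex = "female")
  expect_equal(sum(stf$S + stf$C),
               sum(dplyr::filter(pyr_f, year == 2019)$count))

  expect_error(initialise_states(function(a, t) rep(1.5, length(a)),
                                 pyr, 2019), "above 1")
  expect_error(initialise_states(function(a, t) 0, pyr, 1900), "cover")
})

test_that("a null shock reproduces the baseline trajectory exactly", {
  g <- scenario_grid()
  base <- run_projection(fix_prep, g[1, ], fix_waves)
  null_shock <- g[g$scenario_id == 61, ]
  null_shock$h0 <- 0
  same <- run_projection(fix_prep, null_shock, fix_waves)
  expect_equal(base$cases, same$cases, tolerance = 1e-12)
  expect_equal(base$prevalence_pct, same$prevalence_pct, tolerance = 1e-12)
})

test_that("projection aggregates are internally consistent", {
  res <- run_projection(fix_prep, scenario_grid()[1, ], fix_waves,
                        keep_trajectory = TRUE)
  expect_equal(res$prevalence_pct,
               100 * res$cases / res$population, tolerance = 1e-12)
  expect_setequal(unique(res$year), 2019:2030)
  expect_setequal(unique(res$sex), c("female", "male"))
  traj <- attr(res, "trajectory")
  by_year <- traj |>
    dplyr::group_by(sex, year) |>
    dplyr::summarise(cases = sum(C), .groups = "drop") |>
    dplyr::arrange(sex, year)
  expect_equal(by_year$cases,
               dplyr::arrange(tidy(res), sex, year)$cases, tolerance = 1e-9)
})

test_that("stronger peak increases dominate pointwise, and the gap decays", {
  g <- scenario_grid()
  pick <- function(h0) g[g$h0 == h0 & g$lam == 0.1 & g$delta == 0.5 &
                           g$w_in == 0.1 & g$scenario_id > 0, ]
  r1 <- run_projection(fix_prep, pick(1), fix_waves)
  r5 <- run_projection(fix_prep, pick(5), fix_waves)
  r10 <- run_projection(fix_prep, pick(10), fix_waves)
  base <- run_projection(fix_prep, g[1, ], fix_waves)
  expect_true(all(r5$prevalence_pct >= r1$prevalence_pct - 1e-12))
  expect_true(all(r10$prevalence_pct >= r5$prevalence_pct - 1e-12))
  # scenario-61 analogue exceeds the milder caption scenario at its peak
  peak <- function(r) max(r$prevalence_pct)
  r19 <- run_projection(fix_prep, g[g$scenario_id == 19, ], fix_waves)
  expect_gt(peak(r10), peak(r19))
  # after the last wash-out the excess over baseline shrinks year on year
  gap <- dplyr::inner_join(r10, base, by = c("sex", "year"),
                           suffix = c("", "_base")) |>
    dplyr::filter(year >= 2024) |>
    dplyr::group_by(sex) |>
    dplyr::summarise(shrinking = all(diff(prevalence_pct - prevalence_pct_base)
                                     < 0), .groups = "drop")
  expect_true(all(gap$shrinking))
})

test_that("summaries have the documented shape and rounding", {
  g <- scenario_grid()[1:3, ]
  res <- run_scenario_grid(fix_prep, fix_waves, g)
  sm <- summarise_projection(res, years = c(2020, 2021, 2023, 2030))
  expect_equal(nrow(sm), 3 * 2 * 4)
  one <- summarise_projection(res, years = 2030, scenarios = 2)
  expect_equal(nrow(one), 2)  # one row per sex
  expect_equal(sm$cases_millions, round(sm$cases / 1e6, 2))
  expect_equal(summarise_projection(
    tibble::tibble(scenario_id = 0, sex = "female", year = 2030,
                   cases = 3861234, population = 4e7,
                   prevalence_pct = 9.653085), years = 2030)$cases_millions,
    3.86)
  expect_error(summarise_projection(res, years = 2050), "horizon")
  expect_error(summarise_projection(res, years = 2030, scenarios = 77),
               "unknown scenario")
})

test_that("rate tables survive a writer-reader round trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "rates.csv")
  write_gbd_csv(fix_rates, f)
  back <- read_gbd_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(fix_rates[names(back)]),
               tolerance = 1e-12)

  fp <- file.path(dir, "pop.csv")
  write_population(fix_pop, fp)
  pop2 <- read_population(fp)
  expect_equal(as.data.frame(pop2$pyramid),
               as.data.frame(fix_pop$pyramid[names(pop2$pyramid)]),
               tolerance = 1e-12)
  expect_equal(pop2$births$births, fix_pop$births$births, tolerance = 1e-12)

  fs <- file.path(dir, "weekly.csv")
  write_survstat_csv(fix_covid$series, fs)
  s2 <- read_survstat_csv(fs)
  expect_equal(s2$rate, fix_covid$series$rate, tolerance = 1e-12)
  expect_equal(s2$time, fix_covid$series$time, tolerance = 1e-12)
})

test_that("malformed input files fail with located complaints", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  readr::write_csv(tibble::tibble(measure = "incidence", sex = "female",
                                  age = 10, year = 2000, val = -1), f)
  expect_error(read_gbd_csv(f), "row")
  readr::write_csv(tibble::tibble(measure = "incidence", sex = "female",
                                  age = 10, year = 2000), f)
  expect_error(read_gbd_csv(f), "val")
  readr::write_csv(tibble::tibble(year_week = "2020-XX", rate = 5), f)
  expect_error(read_survstat_csv(f), "unparseable")
})

test_that("ISO week midpoints land where the calendar says", {
  expect_true(iso_week_midpoint("2020-W01") > 2019.99)
  expect_true(iso_week_midpoint("2020-W01") < 2020.03)
  # 2020 had 53 ISO weeks; W53's Thursday was New Year's Eve
  expect_lt(abs(iso_week_midpoint("2020-W53") - (2020 + 365.5 / 366)), 1e-9)
  expect_true(!is.unsorted(iso_week_midpoint(
    sprintf("2021-W%02d", 1:52))))
})

test_that("projection summaries are deterministic end to end", {
  cfg <- synth_config(seed = 1)
  rates <- dplyr::bind_rows(gen_consistent_history(cfg, "female")$rates,
                            gen_consistent_history(cfg, "male")$rates)
  pop <- gen_population(cfg)
  prep2 <- prepare_projection(rates, pop)
  s61 <- scenario_grid()[scenario_grid()$scenario_id == 61, ]
  a <- summarise_projection(run_projection(prep2, s61, fix_waves))
  b <- summarise_projection(run_projection(fix_prep, s61, fix_waves))
  expect_identical(a, b)
})
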