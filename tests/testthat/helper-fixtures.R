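# Shared fixtures, built once per test run.  Everything downstream of the
# generator has known ground truth: remission rate 0.05/yr, RR(t) floored
# at 1, seven Gaussian waves with the default layout.

fix_config <- synth_config(seed = 1)

fix_history <- list(
  female = gen_consistent_history(fix_config, "female"),
  male = gen_consistent_history(fix_config, "male"))

fix_rates <- dplyr::bind_rows(fix_history$female$rates, fix_history$male$rates)

fix_pop <- gen_population(fix_config)

fix_covid <- gen_covid_series(fix_config)

fix_waves <- fit_waves(fix_covid$series, k = 7)

fix_prep <- prepare_projection(fix_rates, fix_pop)

# long rate table -> the (age, time, value) layout estimate_remission expects
rate_tab <- function(history, msr) {
  history$rates |>
    dplyr::filter(.data$measure == msr) |>
    dplyr::transmute(age = .data$age, time = .data$year, value = .data$val)
}

prevalence_tab <- function(history) {
  history$rates |>
    dplyr::filter(.data$measure == "prevalence") |>
    dplyr::transmute(age = .data$age, time = .data$year, p = .data$val)
}
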