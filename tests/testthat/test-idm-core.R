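# An independent single-step oracle, written as explicit flow bookkeeping
# rather than the closed-form update: new cases, deaths in each group and
# remissions are computed separately and moved between stocks.
oracle_step <- function(S, C, i, m0, m1, r, tau) {
  new_cases <- i * tau * S
  deaths_s <- m0 * tau * S
  deaths_c <- m1 * tau * C
  remitted <- r * C
  list(S = S - new_cases - deaths_s + remitted,
       C = C + new_cases - deaths_c - remitted)
}

test_that("compartment step matches the flow-bookkeeping oracle", {
  st <- compartment_state(S = 90, C = 10, time = 2000)
  out <- step_compartments(st, i = 0.05, m0 = 0.01, m1 = 0.014, r = 0.02,
                           tau = 1)
  orc <- oracle_step(90, 10, 0.05, 0.01, 0.014, 0.02, 1)
  expect_equal(out$S, orc$S, tolerance = 1e-12)
  expect_equal(out$C, orc$C, tolerance = 1e-12)

  # inflow only: 10% of susceptibles become cases
  st2 <- compartment_state(S = 100, C = 0, time = 2000)
  out2 <- step_compartments(st2, i = 0.1, m0 = 0, m1 = 0, r = 0, tau = 1)
  expect_equal(out2$S, 90)
  expect_equal(out2$C, 10)
  expect_equal(prevalence(out2), 0.1)

  # symmetric decay leaves the odds unchanged
  st3 <- compartment_state(S = 80, C = 20, time = 2000)
  out3 <- step_compartments(st3, i = 0, m0 = 0.1, m1 = 0.1, r = 0, tau = 1)
  expect_equal(out3$C / out3$S, 20 / 80, tolerance = 1e-12)
})

test_that("step rejects rates that violate the stability guard", {
  st <- compartment_state(S = 10, C = 1, time = 2000)
  expect_error(step_compartments(st, i = 0.6, m0 = 0, m1 = 0, r = 0, tau = 1),
               "smaller step")
  expect_error(step_compartments(st, i = 0.1, m0 = 0, m1 = 0, r = 1.2, tau = 1),
               "remission")
  expect_silent(step_compartments(st, i = 0.6, m0 = 0, m1 = 0, r = 0,
                                  tau = 1 / 52))
})

test_that("odds step agrees with the compartment step over random inputs", {
  set.seed(42)
  worst <- 0
  for (rep in 1:1000) {
    S <- runif(1, 1, 1e6); C <- runif(1, 0.01, S)
    i <- runif(1, 0, 0.4); m0 <- runif(1, 0, 0.4); m1 <- runif(1, 0, 0.4)
    r <- runif(1, 0, 0.5); tau <- runif(1, 0.01, 1)
    if (max(i, m0, m1) * tau >= 0.5) next
    st <- step_compartments(compartment_state(S, C, 0), i, m0, m1, r, tau)
    pi1 <- step_odds(C / S, i, m0, m1, r, tau)
    worst <- max(worst, abs(pi1 - st$C / st$S))
  }
  expect_lt(worst, 1e-10)
})

test_that("identity rates leave the prevalence odds unchanged", {
  expect_equal(step_odds(0.25, 0, 0, 0, 0, tau = 1), 0.25)
  expect_equal(step_odds(0.25, i = 0, m0 = 0.02, m1 = 0.02, r = 0, tau = 1),
               0.25, tolerance = 1e-14)
})

test_that("mass is conserved up to deaths", {
  set.seed(7)
  for (rep in 1:50) {
    S <- runif(96, 0, 1e4); C <- runif(96, 0, 1e3)
    i <- runif(96, 0, 0.05); m0 <- runif(96, 0, 0.05)
    m1 <- runif(96, 0, 0.07); r <- runif(96, 0, 0.1)
    st <- compartment_state(S, C, 2000)
    out <- step_compartments(st, i, m0, m1, r, tau = 1)
    deaths <- sum(S * m0 + C * m1)
    expect_equal(sum(out$S + out$C), sum(S + C) - deaths,
                 tolerance = 1e-9)
  }
})

test_that("remission round trip recovers a random admissible schedule", {
  set.seed(11)
  tau <- 1 / 52
  ages <- 0:10
  n_steps <- 30 * 52  # thirty years, weekly
  i_f <- function(age, time) 0.008 * exp(-0.001 * (age - 25)^2)
  m0_f <- function(age, time) 1e-4 + 1e-5 * age
  m1_f <- function(age, time) 1.4 * m0_f(age, time)
  r_truth <- function(age, time) (0.03 + 0.01 * sin(time)) * tau

  p <- matrix(NA_real_, length(ages), n_steps + 1)
  pi_k <- rep(0.08 / 0.92, length(ages))
  p[, 1] <- pi_k / (1 + pi_k)
  times <- 2000 + (0:n_steps) * tau
  for (k in seq_len(n_steps)) {
    pi_k <- step_odds(pi_k, i_f(ages, times[k]), m0_f(ages, times[k]),
                      m1_f(ages, times[k]), r_truth(ages, times[k]), tau)
    p[, k + 1] <- pi_k / (1 + pi_k)
  }
  p_tab <- tidyr::expand_grid(age = ages, time = times) |>
    dplyr::mutate(p = as.vector(t(p)))
  est <- estimate_remission(p_tab, i_f, m0_f, m1_f, tau = tau)
  truth <- r_truth(est$age, est$time)
  expect_lt(max(abs(est$r - truth)), 1e-8)
  expect_identical(attr(est, "clamped"), 0L)
})

test_that("remission edge cases: stationarity gives zero, p = 0 gives NA", {
  ages <- 0:2
  p_tab <- tidyr::expand_grid(age = ages, time = c(2000, 2001)) |>
    dplyr::mutate(p = 0.1)
  est <- estimate_remission(p_tab, i = function(a, t) 0,
                            m0 = function(a, t) 0.01,
                            m1 = function(a, t) 0.01, tau = 1)
  expect_equal(est$r, rep(0, 3), tolerance = 1e-12)

  p0 <- tidyr::expand_grid(age = 0, time = c(2000, 2001)) |>
    dplyr::mutate(p = 0)
  est0 <- estimate_remission(p0, i = function(a, t) 0,
                             m0 = function(a, t) 0.01,
                             m1 = function(a, t) 0.01, tau = 1)
  expect_true(is.na(est0$r))
})

test_that("cohort advancement shifts, adds births, conserves mass", {
  S <- numeric(96); C <- numeric(96)
  S[41] <- 500; C[41] <- 50  # age 40
  st <- compartment_state(S, C, 2000)
  out <- advance_cohorts(st, births = 0)
  expect_equal(out$S[42], 500)
  expect_equal(out$C[42], 50)
  expect_equal(sum(out$S) + sum(out$C), 550)

  out_b <- advance_cohorts(st, births = 1000)
  expect_equal(out_b$S[1], 1000)
  expect_equal(out_b$C[1], 0)

  # the oldest cohort exits
  S95 <- numeric(96); S95[96] <- 777
  st95 <- compartment_state(S95, numeric(96), 2000)
  out95 <- advance_cohorts(st95, births = 5)
  expect_equal(sum(out95$S + out95$C), 5)

  expect_error(advance_cohorts(st, births = -1), "nonnegative")
})

test_that("halving the step length barely changes year-end prevalence", {
  hist <- fix_history$female
  ages <- 0:95
  run_tau <- function(tau) {
    pi_k <- rep(0.1 / 0.9, length(ages))
    for (k in seq_len(round(1 / tau))) {
      t_k <- 2005 + (k - 1) * tau
      pi_k <- step_odds(pi_k, hist$truth$incidence(ages, t_k),
                        hist$truth$m0(ages, t_k), hist$truth$m1(ages, t_k),
                        0.05 * tau, tau)
    }
    pi_k / (1 + pi_k)
  }
  p_week <- run_tau(1 / 52)
  p_half <- run_tau(1 / 104)
  expect_lt(max(abs(p_week - p_half) / p_half), 1e-3)
})
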