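#' Discrete-time illness-death model with remission
#'
#' The model tracks two living compartments per single-year age cohort:
#' susceptible `S` and diseased `C` (the dead are an absorbing state and
#' leave the system).  Over one step of length `tau` years the adopted
#' first-order scheme is
#' \deqn{S' = S (1 - (i + m_0)\tau) + r C}
#' \deqn{C' = C (1 - m_1 \tau - r) + i \tau S}
#' where `i` is the incidence rate, `m0`/`m1` the mortality rates among the
#' susceptible/diseased (all per person-year) and `r` the per-step remission
#' probability.  The same step can be written directly on the prevalence
#' odds \eqn{\pi = p / (1 - p) = C / S}:
#' \deqn{\pi' = \frac{\pi (1 - m_1\tau - r) + i\tau}{1 - (i + m_0)\tau + r\pi}}
#' Solving the odds recursion for `r` gives the remission estimator used by
#' [estimate_remission()].
#'
#' @name idm_core
NULL

# stability guard: per-step transition probabilities must stay well below 1
check_step_rates <- function(i, m0, m1, r, tau) {
  stopifnot(tau > 0)
  if (any(i < 0) || any(m0 < 0) || any(m1 < 0))
    stop("transition rates must be nonnegative", call. = FALSE)
  if (any(r < 0) || any(r > 1))
    stop("remission probability must lie in [0, 1]", call. = FALSE)
  bad <- c(
    if (any(i * tau >= 0.5)) "i",
    if (any(m0 * tau >= 0.5)) "m0",
    if (any(m1 * tau >= 0.5)) "m1"
  )
  if (length(bad))
    stop("per-step probability ", paste(bad, collapse = ", "),
         " * tau >= 0.5: use a smaller step length tau", call. = FALSE)
  invisible(TRUE)
}

#' Create a compartment state
#'
#' @param S,C numeric vectors of susceptible and diseased counts per age
#'   (ages `0:(length(S) - 1)`).
#' @param time decimal year of the state.
#' @param sex label (`"female"` or `"male"`; free-form).
#' @return A `compartment_state` (tibble with columns `age`, `S`, `C` and
#'   attributes `time` and `sex`).
#' @export
compartment_state <- function(S, C, time, sex = "female") {
  stopifnot(length(S) == length(C))
  if (any(S < 0) || any(C < 0))
    stop("compartment counts must be nonnegative", call. = FALSE)
  out <- tibble::tibble(age = seq_along(S) - 1L, S = as.numeric(S), C = as.numeric(C))
  attr(out, "time") <- time
  attr(out, "sex") <- sex
  attr(out, "clamped") <- 0
  class(out) <- c("compartment_state", class(out))
  out
}

#' Advance a compartment state by one time step
#'
#' Applies the first-order illness-death step (see [idm_core]) to every age
#' cohort.  Rates may be scalars or vectors along the age grid.  Negative
#' results from extreme per-step flows are clamped at zero and the clamped
#' mass accumulated in the `clamped` attribute.
#'
#' @param state a [compartment_state()].
#' @param i,m0,m1 incidence and mortality rates (per person-year).
#' @param r per-step remission probability.
#' @param tau step length in years.
#' @return The state at `time + tau`.
#' @export
step_compartments <- function(state, i, m0, m1, r, tau) {
  check_step_rates(i, m0, m1, r, tau)
  st <- step_sc(state$S, state$C, i, m0, m1, r, tau)
  clamped <- st$clamped
  out <- compartment_state(st$S, st$C,
                           time = attr(state, "time") + tau,
                           sex = attr(state, "sex"))
  attr(out, "clamped") <- attr(state, "clamped") + clamped
  out
}

# bare-metal single step shared by step_compartments and the projection loop
step_sc <- function(S, C, i, m0, m1, r, tau) {
  S1 <- S * (1 - (i + m0) * tau) + r * C
  C1 <- C * (1 - m1 * tau - r) + i * tau * S
  list(S = pmax(S1, 0), C = pmax(C1, 0),
       clamped = sum(pmax(-S1, 0)) + sum(pmax(-C1, 0)))
}

#' Advance prevalence odds by one time step
#'
#' The odds form of the illness-death step: algebraically identical to
#' taking `C/S` after [step_compartments()], but propagates the prevalence
#' odds \eqn{\pi = p/(1-p)} directly, with no dependence on population size.
#'
#' @param pi prevalence odds per age (nonnegative).
#' @inheritParams step_compartments
#' @return Odds at `t + tau`.
#' @export
step_odds <- function(pi, i, m0, m1, r, tau) {
  check_step_rates(i, m0, m1, r, tau)
  if (any(!is.finite(pi)) || any(pi < 0))
    stop("prevalence odds must be finite and nonnegative (p < 1)", call. = FALSE)
  num <- pi * (1 - m1 * tau - r) + i * tau
  den <- 1 - (i + m0) * tau + r * pi
  if (any(den <= 0))
    stop("odds step denominator vanished; prevalence approaching 1", call. = FALSE)
  num / den
}

#' Estimate the per-step remission probability from a prevalence series
#'
#' Inverts the prevalence-odds recursion for `r`: given consecutive
#' prevalence values `p_k`, `p_{k+1}` on the same grid as the rates,
#' \deqn{r_k = \frac{\pi_k (1 - m_1\tau) + i\tau - \pi_{k+1}(1 - (i+m_0)\tau)}
#'                  {\pi_k (\pi_{k+1} + 1)}}
#' with \eqn{\pi = p/(1-p)}.  Cells with `p_k = 0` have no diseased mass to
#' remit and are returned as `NA`.  Estimates falling outside `[0, 1]`
#' (possible when the series was not generated by the model) are clamped,
#' and the number of clamped cells is reported in the `clamped` attribute.
#'
#' @param p data frame with columns `age`, `time`, `p` (prevalence
#'   proportion in `[0, 1)`), on a regular time grid of spacing `tau`.
#' @param i,m0,m1 data frames with the same `age`/`time` grid and a `value`
#'   column, or vectorised functions `f(age, time)` returning rates.
#' @param tau step length (years) between consecutive time points.
#' @return A tibble `age`, `time`, `r` where `time` labels the start of each
#'   step (one fewer time point than `p`), with attribute `clamped`.
#' @export
estimate_remission <- function(p, i, m0, m1, tau) {
  stopifnot(all(c("age", "time", "p") %in% names(p)))
  if (any(p$p < 0 | p$p >= 1))
    stop("prevalence must lie in [0, 1)", call. = FALSE)
  rate_at <- function(x, age, time) {
    if (is.function(x)) return(x(age, time))
    key <- paste(x$age, signif(x$time, 10))
    val <- x$value[match(paste(age, signif(time, 10)), key)]
    if (any(is.na(val)))
      stop("rate grid does not cover the prevalence grid", call. = FALSE)
    val
  }
  out <- p |>
    dplyr::arrange(.data$age, .data$time) |>
    dplyr::group_by(.data$age) |>
    dplyr::mutate(pi = .data$p / (1 - .data$p),
                  pi_next = dplyr::lead(.data$pi)) |>
    dplyr::filter(!is.na(.data$pi_next)) |>
    dplyr::ungroup()
  iv <- rate_at(i, out$age, out$time)
  m0v <- rate_at(m0, out$age, out$time)
  m1v <- rate_at(m1, out$age, out$time)
  r <- (out$pi * (1 - m1v * tau) + iv * tau -
          out$pi_next * (1 - (iv + m0v) * tau)) / (out$pi * (out$pi_next + 1))
  r[out$pi == 0] <- NA_real_
  clamped <- sum(r < 0 | r > 1, na.rm = TRUE)
  r <- pmin(pmax(r, 0), 1)
  res <- tibble::tibble(age = out$age, time = out$time, r = r)
  attr(res, "clamped") <- clamped
  res
}

#' Shift all cohorts up one year of age
#'
#' Called once per whole simulated year: every cohort's `(S, C)` moves to
#' the next single-year age bin, the oldest cohort exits the analysis, and
#' the year's births enter at age 0 as susceptible.
#'
#' @param state a [compartment_state()].
#' @param births number of births entering at age 0 (must be nonnegative).
#' @return The aged state (same `time`).
#' @export
advance_cohorts <- function(state, births) {
  if (births < 0) stop("births must be nonnegative", call. = FALSE)
  n <- nrow(state)
  S <- c(births, state$S[-n])
  C <- c(0, state$C[-n])
  out <- compartment_state(S, C, time = attr(state, "time"),
                           sex = attr(state, "sex"))
  attr(out, "clamped") <- attr(state, "clamped")
  out
}

#' Prevalence of a compartment state
#'
#' @param state a [compartment_state()].
#' @param by_age if `TRUE`, per-age prevalence; otherwise the crude
#'   all-age proportion `sum(C) / sum(S + C)`.
#' @return Proportion(s) in `[0, 1]`.
#' @export
prevalence <- function(state, by_age = FALSE) {
  if (by_age) {
    tot <- state$S + state$C
    ifelse(tot > 0, state$C / tot, 0)
  } else {
    sum(state$C) / sum(state$S + state$C)
  }
}
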