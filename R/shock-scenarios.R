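#' The 82-scenario grid of incidence-shock parameters
#'
#' Scenario 0 is the baseline (no shock).  Scenarios 1-81 enumerate the
#' full factorial of the shock parameters:
#' wash-in/wash-out fraction `w` in \{0.1, 0.2, 0.3\} (the two are tied),
#' delay fraction `delta` in \{0, 0.25, 0.5\}, peak relative incidence
#' increase `h0` in \{1, 5, 10\} (i.e. +100\%, +500\%, +1000\%) and
#' between-wave exponential decay `lambda` in \{0.1, 0.2, 0.3\}.  The id
#' is `27 a + 9 c + 3 b + d + 1` where `a`, `c`, `b`, `d` index `h0`,
#' `lambda`, `delta` and `w` ascending from 0.
#'
#' @return Tibble of 82 rows: `scenario_id`, `w_in`, `w_out`, `delta`,
#'   `h0`, `lam`.
#' @export
scenario_grid <- function() {
  h0_lv <- c(1, 5, 10); lam_lv <- c(0.1, 0.2, 0.3)
  delta_lv <- c(0, 0.25, 0.5); w_lv <- c(0.1, 0.2, 0.3)
  idx <- expand.grid(d = 0:2, b = 0:2, c = 0:2, a = 0:2)
  grid <- tibble::tibble(
    scenario_id = 27L * idx$a + 9L * idx$c + 3L * idx$b + idx$d + 1L,
    w_in = w_lv[idx$d + 1], w_out = w_lv[idx$d + 1],
    delta = delta_lv[idx$b + 1], h0 = h0_lv[idx$a + 1],
    lam = lam_lv[idx$c + 1])
  dplyr::bind_rows(
    tibble::tibble(scenario_id = 0L, w_in = 0, w_out = 0,
                   delta = 0, h0 = 0, lam = 0),
    dplyr::arrange(grid, .data$scenario_id)) |>
    dplyr::select("scenario_id", "w_in", "w_out", "delta", "h0", "lam")
}

#' Peak incidence increase for a given wave
#'
#' The shock magnitude diminishes exponentially from one wave to the next:
#' \eqn{h_w = h_0 e^{-\lambda (w - 1)}}, reflecting gradual adaptation.
#'
#' @param h0 peak relative increase at the first wave.
#' @param lam decay constant per wave.
#' @param w wave index (1-based).
#' @return Relative incidence increase at wave `w`.
#' @export
wave_magnitude <- function(h0, lam, w) {
  stopifnot(all(w >= 1))
  h0 * exp(-lam * (w - 1))
}

#' Build the incidence-shock function for one scenario
#'
#' For each wave `w` with FWHM interval `[s, e]` of duration `D`, the
#' relative incidence increase rises linearly from 0 at the wave start `s`
#' to `h_w` at `s + w_in * D` (wash-in), stays at `h_w` through
#' `e + delta * D` (the elevation outlasts the infection wave by the
#' delay), then falls linearly back to 0 over `w_out * D` (wash-out).
#' Contributions of overlapping waves are summed.  A `"triangle"` shape
#' starts the wash-out immediately after the wash-in peak instead.
#'
#' @param params one row of [scenario_grid()] (or any list with `w_in`,
#'   `w_out`, `delta`, `h0`, `lam`).
#' @param waves a [fit_waves()] result or tibble with `mu`, `sigma` (its
#'   FWHM intervals define the wave envelopes); ignored when `h0 = 0`.
#' @param shape `"trapezoid"` (default) or `"triangle"`.
#' @return A `shock_function`: vectorised `A(t)` giving the relative
#'   incidence increase at decimal year `t` (0 outside all envelopes),
#'   with the per-wave node table in attribute `"nodes"`.
#' @export
build_shock <- function(params, waves = NULL, shape = c("trapezoid", "triangle")) {
  shape <- match.arg(shape)
  if (params$h0 == 0) {
    f <- function(t) rep(0, length(t))
    attr(f, "nodes") <- tibble::tibble(wave = integer(), t0 = numeric(),
                                       t1 = numeric(), t2 = numeric(),
                                       t3 = numeric(), h = numeric())
    class(f) <- c("shock_function", class(f))
    return(f)
  }
  iv <- wave_intervals(waves)
  if (any(iv$duration <= 0)) stop("degenerate wave interval", call. = FALSE)
  nodes <- iv |>
    dplyr::mutate(
      h = wave_magnitude(params$h0, params$lam, .data$wave),
      t0 = .data$start,
      t1 = .data$start + params$w_in * .data$duration,
      t2 = if (shape == "trapezoid")
        .data$end + params$delta * .data$duration else .data$t1,
      t3 = .data$t2 + params$w_out * .data$duration) |>
    dplyr::select("wave", "t0", "t1", "t2", "t3", "h")
  f <- function(t) {
    A <- numeric(length(t))
    for (w in seq_len(nrow(nodes))) {
      nd <- nodes[w, ]
      up <- (t - nd$t0) / (nd$t1 - nd$t0)
      down <- (nd$t3 - t) / (nd$t3 - nd$t2)
      A <- A + nd$h * pmax(0, pmin(1, up, down))
    }
    A
  }
  attr(f, "nodes") <- nodes
  class(f) <- c("shock_function", class(f))
  f
}

#' Apply an incidence shock to a baseline incidence rule
#'
#' The effective incidence is the baseline scaled by the relative increase,
#' uniformly over age and sex:
#' \eqn{i_{eff}(a, t) = i_{base}(a, t)\,(1 + A(t))}, so `A = 1` doubles the
#' incidence (+100\%) and `A = 10` gives an 11-fold rate (+1000\%).
#'
#' @param base vectorised baseline incidence `f(age, time)`.
#' @param shock a [build_shock()] result.
#' @return A vectorised effective incidence function `f(age, time)`.
#' @export
apply_shock <- function(base, shock) {
  function(age, time) base(age, time) * (1 + shock(time))
}

#' @export
print.shock_function <- function(x, ...) {
  nd <- attr(x, "nodes")
  cat("<shock_function>", nrow(nd), "wave(s)\n")
  if (nrow(nd)) print(nd)
  invisible(x)
}
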