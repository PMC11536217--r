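#' Full width at half maximum of a Gaussian wave
#'
#' For a Gaussian peak with standard deviation `sigma`, the width of the
#' interval over which the curve exceeds half its maximum is
#' \eqn{\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma \approx 2.3548\,\sigma}.
#' Used to delineate the duration of each epidemic wave.
#'
#' @param sigma Gaussian standard deviation (years); must be positive.
#' @return Width in the same units as `sigma`.
#' @export
fwhm <- function(sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  2 * sqrt(2 * log(2)) * sigma
}

#' Decompose a weekly incidence series into Gaussian waves
#'
#' Fits a sum of `k` Gaussians
#' \deqn{\mathrm{rate}(t) \approx \sum_w A_w \exp\!\big(-(t-\mu_w)^2 / (2\sigma_w^2)\big)}
#' to a weekly epidemic incidence series by constrained nonlinear least
#' squares (Levenberg-Marquardt with positivity bounds).  Unless starting
#' values are supplied, the fit is initialised from the `k` most prominent
#' local maxima of the series (prominence = height above the higher of the
#' two flanking minima), with each `sigma` seeded from the peak's
#' half-height span.
#'
#' @param series data frame with columns `time` (decimal years) and `rate`.
#' @param k number of waves to fit.
#' @param init optional `wave_set` (or tibble with `amplitude`, `mu`,
#'   `sigma`) of starting values.
#' @param baseline if `TRUE`, also fit a constant offset (default `FALSE`:
#'   incidence is assumed to decay to about zero between waves).
#' @param maxiter iteration budget for the optimizer.
#' @return A `wave_set`: tibble of fitted waves ordered by centre `mu`, with
#'   columns `wave`, `amplitude`, `mu`, `sigma`, `fwhm`, `start`, `end`, and
#'   attributes `rss`, `baseline` and the input `series`.
#' @export
fit_waves <- function(series, k, init = NULL, baseline = FALSE,
                      maxiter = 500) {
  stopifnot(all(c("time", "rate") %in% names(series)), k >= 1)
  series <- dplyr::arrange(series, .data$time)
  t <- series$time; y <- series$rate
  if (length(t) < 3 * k)
    stop("series too short: need at least 3 observations per wave", call. = FALSE)

  if (is.null(init)) {
    pk <- find_peaks(t, y, k)
    amps <- pk$height; mus <- pk$time; sigmas <- pk$sigma
  } else {
    stopifnot(nrow(init) == k)
    amps <- init$amplitude; mus <- init$mu; sigmas <- init$sigma
  }
  off0 <- if (baseline) max(min(y), 0) * 0.5 else numeric(0)

  mix <- function(par) {
    A <- par[seq_len(k)]; mu <- par[k + seq_len(k)]; sg <- par[2 * k + seq_len(k)]
    f <- rowSums(vapply(seq_len(k),
                        function(w) A[w] * exp(-(t - mu[w])^2 / (2 * sg[w]^2)),
                        numeric(length(t))))
    if (baseline) f <- f + par[3 * k + 1]
    f
  }
  par0 <- c(amps, mus, sigmas, off0)
  span <- diff(range(t))
  lower <- c(rep(1e-12, k), rep(min(t) - span, k), rep(1e-4, k),
             if (baseline) 0)
  upper <- c(rep(max(y) * 10 + 1, k), rep(max(t) + span, k), rep(span, k),
             if (baseline) max(y))
  res <- minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                            fn = function(par) y - mix(par),
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, maxfev = 100000))
  if (res$info == 0 || res$info == 9)
    stop("wave fit did not converge within the iteration budget (best RSS ",
         format(res$deviance), ")", call. = FALSE)
  par <- res$par
  waves <- tibble::tibble(amplitude = par[seq_len(k)],
                          mu = par[k + seq_len(k)],
                          sigma = par[2 * k + seq_len(k)]) |>
    dplyr::arrange(.data$mu) |>
    dplyr::mutate(wave = dplyr::row_number(),
                  fwhm = fwhm(.data$sigma),
                  start = .data$mu - .data$fwhm / 2,
                  end = .data$mu + .data$fwhm / 2) |>
    dplyr::select("wave", "amplitude", "mu", "sigma", "fwhm", "start", "end")
  attr(waves, "rss") <- res$deviance
  attr(waves, "baseline") <- if (baseline) par[3 * k + 1] else 0
  attr(waves, "series") <- series
  class(waves) <- c("wave_set", class(waves))
  waves
}

# prominence-ranked local maxima with half-height span widths
find_peaks <- function(t, y, k) {
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (y[1] > y[2]) is_max <- c(1L, is_max)
  if (y[n] > y[n - 1]) is_max <- c(is_max, n)
  prom <- vapply(is_max, function(i) {
    left <- if (i > 1) min(y[1:i]) else y[1]
    right <- if (i < n) min(y[i:n]) else y[n]
    y[i] - max(left, right)
  }, numeric(1))
  keep <- order(prom, decreasing = TRUE)
  if (length(is_max) < k)
    stop("only ", length(is_max), " local maxima found; ",
         "reduce the number of waves k", call. = FALSE)
  idx <- sort(is_max[keep[seq_len(k)]])
  sigma <- vapply(idx, function(i) {
    half <- y[i] / 2
    l <- i; while (l > 1 && y[l] > half) l <- l - 1
    r <- i; while (r < n && y[r] > half) r <- r + 1
    # half-height span approximates the FWHM
    max(t[r] - t[l], 2 * (t[2] - t[1])) / (2 * sqrt(2 * log(2)))
  }, numeric(1))
  list(time = t[idx], height = y[idx], sigma = sigma)
}

#' Wave intervals delineated by FWHM
#'
#' Each wave's interval is \eqn{[\mu - \mathrm{FWHM}/2,\ \mu + \mathrm{FWHM}/2]};
#' overlap between adjacent fitted waves is allowed.
#'
#' @param waves a `wave_set` from [fit_waves()] or a tibble with `mu`, `sigma`.
#' @return Tibble `wave`, `start`, `end`, `duration` ordered by centre.
#' @export
wave_intervals <- function(waves) {
  stopifnot(all(c("mu", "sigma") %in% names(waves)))
  waves |>
    dplyr::arrange(.data$mu) |>
    dplyr::transmute(wave = dplyr::row_number(),
                     start = .data$mu - fwhm(.data$sigma) / 2,
                     end = .data$mu + fwhm(.data$sigma) / 2,
                     duration = fwhm(.data$sigma))
}

#' Evaluate a Gaussian wave mixture
#'
#' @param waves tibble with `amplitude`, `mu`, `sigma`.
#' @param time decimal years.
#' @param baseline constant offset added to the mixture.
#' @return Incidence rate at each `time`.
#' @export
eval_waves <- function(waves, time, baseline = 0) {
  m <- vapply(seq_len(nrow(waves)), function(w)
    waves$amplitude[w] * exp(-(time - waves$mu[w])^2 / (2 * waves$sigma[w]^2)),
    numeric(length(time)))
  rowSums(matrix(m, nrow = length(time))) + baseline
}

#' @export
print.wave_set <- function(x, ...) {
  cat("<wave_set>", nrow(x), "Gaussian waves, RSS =",
      format(attr(x, "rss")), "\n")
  NextMethod()
}
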